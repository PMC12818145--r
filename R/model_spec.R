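#' Declare a composite path model
#'
#' A model is a set of latent variables, each measured by a block of observed
#' indicators, plus a set of directed structural paths between latents. The
#' structural part is the recursive system \eqn{\eta = B\eta + \Gamma\xi +
#' \zeta}; the measurement part attaches each indicator to exactly one latent,
#' reflectively (indicator = loading x latent + error) or formatively.
#'
#' The role of each latent (exogenous vs endogenous) is *derived* from the
#' adjacency: a latent with no incoming path is exogenous. Users never declare
#' roles, so role/adjacency contradictions cannot arise.
#'
#' @param latents list of blocks, each a list with elements `name` (string),
#'   `indicators` (character vector, non-empty) and optionally `mode`
#'   (`"reflective"`, the default, or `"formative"`).
#' @param paths list of length-2 character vectors `c(source, target)` (or a
#'   two-column matrix/data frame). The implied graph must be acyclic.
#' @param ipma_target optional name of the endogenous latent that the
#'   importance-performance analysis will target.
#' @param scale_bounds optional named list, `indicator = c(min, max)`, giving
#'   theoretical bounds used for 0-100 rescaling; `min < max` required.
#' @return An object of class `pls_model`.
#' @examples
#' spec <- model_spec(
#'   latents = list(list(name = "A", indicators = c("a1", "a2")),
#'                  list(name = "B", indicators = "b1")),
#'   paths = list(c("A", "B")))
#' topo_order(spec)
#' @export
model_spec <- function(latents, paths = list(), ipma_target = NULL,
                       scale_bounds = NULL) {
  if (!is.list(latents) || length(latents) == 0)
    stop_spec("`latents` must be a non-empty list of blocks")
  latents <- lapply(latents, function(l) {
    if (is.null(l$name) || !nzchar(l$name))
      stop_spec("every latent needs a non-empty `name`")
    ind <- as.character(l$indicators)
    if (length(ind) == 0)
      stop_spec("latent '%s' has an empty indicator block", l$name)
    mode <- if (is.null(l$mode)) "reflective" else match.arg(l$mode,
                                                 c("reflective", "formative"))
    list(name = as.character(l$name), mode = mode, indicators = ind)
  })
  lnames <- vapply(latents, `[[`, "", "name")
  if (anyDuplicated(lnames))
    stop_spec("duplicate latent name: %s", lnames[duplicated(lnames)][1])

  all_ind <- unlist(lapply(latents, `[[`, "indicators"))
  if (anyDuplicated(all_ind))
    stop_spec("indicator '%s' is assigned to more than one latent block",
              all_ind[duplicated(all_ind)][1])

  edges <- normalize_paths(paths)
  bad <- setdiff(c(edges[, 1], edges[, 2]), lnames)
  if (length(bad))
    stop_spec("path refers to unknown latent '%s'", bad[1])
  if (nrow(edges) && anyDuplicated(paste(edges[, 1], edges[, 2])))
    stop_spec("duplicate structural path declared")

  # roles derived from adjacency
  endo <- lnames %in% edges[, 2]
  for (j in seq_along(latents))
    latents[[j]]$role <- if (endo[j]) "endogenous" else "exogenous"

  spec <- structure(list(latents = latents, paths = edges,
                         ipma_target = ipma_target,
                         scale_bounds = scale_bounds),
                    class = "pls_model")
  topo_order(spec)  # errors on a cycle, reporting it

  if (!is.null(ipma_target)) {
    if (!ipma_target %in% lnames)
      stop_spec("ipma_target '%s' is not a latent in the model", ipma_target)
    if (!endo[match(ipma_target, lnames)])
      stop_spec("ipma_target '%s' must be endogenous (have an incoming path)",
                ipma_target)
  }
  if (!is.null(scale_bounds)) {
    if (is.null(names(scale_bounds)) || any(!nzchar(names(scale_bounds))))
      stop_spec("scale_bounds must be a named list")
    unknown <- setdiff(names(scale_bounds), all_ind)
    if (length(unknown))
      stop_spec("scale_bounds given for unknown indicator '%s'", unknown[1])
    for (nm in names(scale_bounds)) {
      b <- as.numeric(scale_bounds[[nm]])
      if (length(b) != 2 || !all(is.finite(b)) || b[1] >= b[2])
        stop_spec("scale_bounds for '%s' must be c(min, max) with min < max",
                  nm)
      spec$scale_bounds[[nm]] <- b
    }
  }
  spec
}

normalize_paths <- function(paths) {
  if (is.matrix(paths) || is.data.frame(paths)) {
    paths <- as.matrix(paths)
    if (length(paths) && ncol(paths) != 2)
      stop_spec("`paths` matrix must have two columns (source, target)")
    edges <- matrix(as.character(paths), ncol = 2)
  } else if (is.list(paths)) {
    if (length(paths) == 0) {
      edges <- matrix(character(0), ncol = 2)
    } else {
      ok <- vapply(paths, function(p) length(p) == 2, TRUE)
      if (!all(ok)) stop_spec("each path must be c(source, target)")
      edges <- do.call(rbind, lapply(paths, as.character))
    }
  } else stop_spec("`paths` must be a list or a two-column matrix")
  colnames(edges) <- c("source", "target")
  edges
}

#' @export
print.pls_model <- function(x, ...) {
  cat("Composite path model:", length(x$latents), "latent variable(s),",
      length(indicator_names(x)), "indicator(s),",
      nrow(x$paths), "path(s)\n")
  for (l in x$latents)
    cat(sprintf("  %s [%s, %s]: %s\n", l$name, l$role, l$mode,
                paste(l$indicators, collapse = ", ")))
  if (nrow(x$paths))
    cat("Paths:", paste(x$paths[, 1], "->", x$paths[, 2], collapse = "; "),
        "\n")
  if (!is.null(x$ipma_target)) cat("IPMA target:", x$ipma_target, "\n")
  invisible(x)
}

latent_names <- function(spec) vapply(spec$latents, `[[`, "", "name")

indicator_names <- function(spec)
  unlist(lapply(spec$latents, `[[`, "indicators"), use.names = FALSE)

# named character: indicator -> latent
indicator_latent_map <- function(spec) {
  out <- unlist(lapply(spec$latents, function(l)
    stats::setNames(rep(l$name, length(l$indicators)), l$indicators)))
  out
}

# list per latent name of its parents (character(0) when exogenous)
parents_of <- function(spec) {
  ln <- latent_names(spec)
  out <- stats::setNames(vector("list", length(ln)), ln)
  for (nm in ln) out[[nm]] <- spec$paths[spec$paths[, 2] == nm, 1]
  out
}

#' Topological order of the latent variables
#'
#' Kahn's algorithm with ties broken by declaration order, so the result is
#' deterministic: every path source precedes its target, and latents that are
#' unconstrained relative to each other keep their declared order. Used to
#' estimate the structural system equation by equation and to accumulate
#' total effects.
#'
#' @param spec a `pls_model`.
#' @return Character vector: a permutation of the latent names.
#' @export
topo_order <- function(spec) {
  ln <- latent_names(spec)
  edges <- spec$paths
  indeg <- stats::setNames(integer(length(ln)), ln)
  if (nrow(edges)) {
    tab <- table(edges[, 2])
    indeg[names(tab)] <- as.integer(tab)
  }
  remaining <- ln
  out <- character(0)
  while (length(remaining)) {
    avail <- remaining[indeg[remaining] == 0]
    if (!length(avail)) {
      cyc <- find_cycle(remaining, edges)
      stop_spec("structural model contains a cycle: %s",
                paste(cyc, collapse = " -> "))
    }
    nxt <- avail[1]  # declaration order preserved by `remaining`
    out <- c(out, nxt)
    remaining <- setdiff(remaining, nxt)
    kids <- edges[edges[, 1] == nxt, 2]
    for (k in kids) indeg[k] <- indeg[k] - 1L
  }
  out
}

# walk forward inside the unresolvable node set until a node repeats
find_cycle <- function(nodes, edges) {
  cur <- nodes[1]
  seen <- character(0)
  while (!cur %in% seen) {
    seen <- c(seen, cur)
    nxt <- edges[edges[, 1] == cur & edges[, 2] %in% nodes, 2]
    cur <- nxt[1]
  }
  c(seen[which(seen == cur):length(seen)], cur)
}

#' Read / write a model specification as JSON
#'
#' The on-disk dialect mirrors the constructor: top-level keys `latents`
#' (list of `{name, mode, indicators}`), `paths` (list of `[source, target]`
#' pairs), and optional `ipma_target` and `scale_bounds`
#' (`{indicator: [min, max]}`). Indicator names must match CSV column headers
#' exactly (case-sensitive). `write_model_spec()` followed by
#' `read_model_spec()` round-trips to an identical model.
#'
#' @param path file path of the JSON document.
#' @return `read_model_spec()` returns a validated `pls_model`.
#' @export
read_model_spec <- function(path) {
  if (!file.exists(path)) stop_spec("model file not found: %s", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$latents))
    stop_spec("model document has no `latents` section")
  latents <- lapply(doc$latents, function(l)
    list(name = l$name, mode = l$mode,
         indicators = unlist(l$indicators, use.names = FALSE)))
  paths <- lapply(doc$paths, function(p) unlist(p, use.names = FALSE))
  bounds <- if (is.null(doc$scale_bounds)) NULL else
    lapply(doc$scale_bounds, function(b) as.numeric(unlist(b)))
  model_spec(latents = latents, paths = if (is.null(paths)) list() else paths,
             ipma_target = doc$ipma_target, scale_bounds = bounds)
}

#' @rdname read_model_spec
#' @param spec a `pls_model` to serialize.
#' @export
write_model_spec <- function(spec, path) {
  doc <- list(
    latents = lapply(spec$latents, function(l)
      list(name = l$name, mode = l$mode, indicators = as.list(l$indicators))),
    paths = if (nrow(spec$paths))
      lapply(seq_len(nrow(spec$paths)),
             function(i) as.list(unname(spec$paths[i, ]))) else list())
  if (!is.null(spec$ipma_target)) doc$ipma_target <- spec$ipma_target
  if (!is.null(spec$scale_bounds))
    doc$scale_bounds <- lapply(spec$scale_bounds, as.list)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
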