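#' Bundle aligned context embeddings
#'
#' Embeddings trained in different barrier contexts on the same room
#' footprint (see [barrier_context_envs()]): state `i` means the same
#' position in every context, so the alignment map is the identity. All
#' embeddings must have identical dimensions.
#'
#' @param A,B,phi `dsi_embedding` objects for the two single-barrier
#'   contexts and the empty context.
#' @param AB Optional embedding trained directly in the two-barrier context
#'   (ground truth for comparisons).
#' @return A `context_set`.
#' @export
context_set <- function(A, B, phi, AB = NULL) {
  embs <- list(A = A, B = B, phi = phi)
  if (!is.null(AB)) embs$AB <- AB
  dims <- lapply(embs, function(e) dim(e$X))
  if (length(unique(lapply(dims, paste, collapse = "x"))) != 1) {
    abort("context embeddings have misaligned footprints (differing dimensions).")
  }
  structure(embs, class = "context_set")
}

#' Compose an embedding for the unseen two-barrier context
#'
#' Per position and unit, `x(A) + x(B) - x(phi)`, clipped at zero, applied
#' to both the state matrix X and the goal matrix W. The relationship of
#' phi to B (adding one barrier) is transferred onto A, yielding vectors
#' for the never-experienced context with both barriers.
#'
#' @param ctx A [context_set()].
#' @return A `dsi_embedding` (variant `"composed"`).
#' @export
compose_context <- function(ctx) {
  stopifnot(inherits(ctx, "context_set"))
  X <- pmax(ctx$A$X + ctx$B$X - ctx$phi$X, 0)
  W <- pmax(ctx$A$W + ctx$B$W - ctx$phi$W, 0)
  as_dsi_embedding(X, W, variant = "composed", labels = ctx$A$labels)
}

#' Per-unit representational distance between two contexts
#'
#' The distance of unit `k` is the summed squared difference of its state
#' values at aligned positions: `sum_i (x_k(i; X) - x_k(i; Y))^2`.
#'
#' @param ctx_x,ctx_y `dsi_embedding` objects on aligned footprints.
#' @param source `"X"` (default) or `"W"`.
#' @return A tibble `unit`, `distance`, sorted by unit.
#' @export
unit_distance <- function(ctx_x, ctx_y, source = c("X", "W")) {
  source <- match.arg(source)
  Mx <- ctx_x[[source]]
  My <- ctx_y[[source]]
  stopifnot(all(dim(Mx) == dim(My)))
  tibble::tibble(unit = seq_len(ncol(Mx)),
                 distance = colSums((Mx - My)^2))
}

#' Compose only a subset of units
#'
#' The composition `A + B - phi` is applied on the selected units only;
#' all other units are copied from context A. Selection is either an
#' explicit unit set or the `top_k` units by representational distance
#' between contexts B and phi (where the second barrier's effect lives).
#'
#' @param ctx A [context_set()].
#' @param units Optional integer vector of units to compose.
#' @param top_k Optional number of highest-distance units to compose
#'   (ignored when `units` is given).
#' @return A `dsi_embedding` (variant `"composed-partial"`). An empty
#'   selection returns context A with a warning.
#' @export
compose_partial <- function(ctx, units = NULL, top_k = NULL) {
  stopifnot(inherits(ctx, "context_set"))
  D <- ncol(ctx$A$X)
  if (is.null(units)) {
    if (is.null(top_k)) abort("supply `units` or `top_k`.")
    stopifnot(top_k >= 1)
    d <- unit_distance(ctx$B, ctx$phi)
    units <- d$unit[order(-d$distance)][seq_len(min(top_k, D))]
  }
  units <- unique(as.integer(units))
  if (length(units) == 0) {
    warn("empty unit subset; returning context A unchanged.")
    return(as_dsi_embedding(ctx$A$X, ctx$A$W, variant = "composed-partial",
                            labels = ctx$A$labels))
  }
  stopifnot(all(units >= 1), all(units <= D))
  X <- ctx$A$X
  W <- ctx$A$W
  X[, units] <- pmax(ctx$A$X[, units] + ctx$B$X[, units] - ctx$phi$X[, units], 0)
  W[, units] <- pmax(ctx$A$W[, units] + ctx$B$W[, units] - ctx$phi$W[, units], 0)
  out <- as_dsi_embedding(X, W, variant = "composed-partial",
                          labels = ctx$A$labels)
  attr(out, "units") <- units
  out
}

#' Representational distance of grid versus non-grid units
#'
#' Joins the per-unit B-vs-phi representational distance with grid labels
#' computed in the empty context and reports group means. The expectation
#' from the composition analysis is that context information concentrates
#' in non-grid units (non-grid mean > grid mean).
#'
#' @param ctx A [context_set()].
#' @param gridness_labels Tibble from [classify_grid_units()] run on
#'   `ctx$phi` (columns `unit`, `is_grid`).
#' @return A tibble `unit`, `distance`, `is_grid` with attribute
#'   `group_means` (tibble `group`, `n`, `mean_distance`; `NA` mean for an
#'   empty group, with a warning).
#' @export
grid_vs_nongrid_distance <- function(ctx, gridness_labels) {
  stopifnot(inherits(ctx, "context_set"))
  d <- unit_distance(ctx$B, ctx$phi)
  tab <- dplyr::left_join(d, gridness_labels[, c("unit", "is_grid")],
                          by = "unit")
  means <- tab |>
    dplyr::group_by(group = ifelse(.data$is_grid, "grid", "nongrid")) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_distance = mean(.data$distance), .groups = "drop")
  for (g in c("grid", "nongrid")) {
    if (!g %in% means$group) {
      warn(sprintf("no %s units; group mean undefined.", g))
      means <- dplyr::bind_rows(
        means, tibble::tibble(group = g, n = 0L, mean_distance = NA_real_))
    }
  }
  attr(tab, "group_means") <- means
  tab
}
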