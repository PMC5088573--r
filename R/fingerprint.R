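#' Band profile of a rep-PCR fingerprint
#'
#' A ladder-normalized (GTG)5 fingerprint: fragment sizes in bp and the
#' corresponding densitometric band intensities for one strain.
#'
#' @param strain_id Single strain label.
#' @param positions Numeric vector of fragment sizes (bp), strictly increasing.
#' @param intensities Non-negative numeric vector, same length as `positions`.
#' @return An object of class `band_profile`.
#' @export
band_profile <- function(strain_id, positions, intensities) {
  stopifnot(length(strain_id) == 1L, length(positions) == length(intensities))
  positions <- as.numeric(positions)
  intensities <- as.numeric(intensities)
  if (length(positions) && any(diff(positions) <= 0)) {
    stop("band positions must be strictly increasing")
  }
  if (any(intensities < 0)) stop("band intensities must be non-negative")
  structure(
    list(strain_id = as.character(strain_id),
         positions = positions, intensities = intensities),
    class = "band_profile"
  )
}

#' @export
print.band_profile <- function(x, ...) {
  cat("<band_profile> strain", x$strain_id, "-", length(x$positions),
      "bands in [", min(x$positions), ",", max(x$positions), "] bp\n")
  invisible(x)
}

#' Eliminate bands outside the calibrated size window
#'
#' Bands larger than `max_bp` or smaller than `min_bp` are removed before
#' similarity analysis to avoid false clustering from poorly resolved
#' fragments. The interval is closed: bands at exactly 300 or 5000 bp are
#' kept.
#'
#' @param profile A [band_profile()].
#' @param min_bp,max_bp Size window in bp (defaults 300 and 5000).
#' @return A `band_profile` with only in-window bands; order preserved.
#'   Profiles left with zero bands are returned flagged
#'   (`attr(, "empty") = TRUE`) with a warning, so callers can exclude them.
#' @export
filter_bands <- function(profile, min_bp = 300, max_bp = 5000) {
  stopifnot(inherits(profile, "band_profile"), min_bp < max_bp)
  keep <- profile$positions >= min_bp & profile$positions <= max_bp
  out <- band_profile(profile$strain_id,
                      profile$positions[keep], profile$intensities[keep])
  if (length(out$positions) == 0L) {
    warning("strain ", profile$strain_id,
            ": no bands remain in [", min_bp, ", ", max_bp,
            "] bp; excluded from similarity analysis")
    attr(out, "empty") <- TRUE
  }
  out
}

# Shared raster grid: uniform in log10(bp), since gel migration distance is
# approximately linear in log fragment size.
raster_grid <- function(min_bp = 300, max_bp = 5000, n_grid = 1000L) {
  seq(log10(min_bp), log10(max_bp), length.out = n_grid)
}

#' Rasterize a band profile to a densitometric curve
#'
#' Projects bands onto a common log10(bp) grid as a sum of Gaussian peaks,
#' one per band, weighted by intensity. The kernel standard deviation is
#' `tolerance` times the grid span, mirroring the band-matching tolerance of
#' curve-based fingerprint comparison.
#'
#' @param profile A [band_profile()] (size-filtered).
#' @param tolerance Band-matching tolerance as a fraction of the grid span
#'   (default 0.005, i.e. 0.5%).
#' @param min_bp,max_bp,n_grid Grid specification; see [raster_grid()].
#' @return Numeric vector of length `n_grid`.
#' @export
rasterize_profile <- function(profile, tolerance = 0.005,
                              min_bp = 300, max_bp = 5000, n_grid = 1000L) {
  stopifnot(inherits(profile, "band_profile"))
  if (length(profile$positions) == 0L) stop("cannot rasterize an empty profile")
  grid <- raster_grid(min_bp, max_bp, n_grid)
  sigma <- tolerance * (grid[n_grid] - grid[1L])
  peaks <- exp(-outer(grid, log10(profile$positions), "-")^2 / (2 * sigma^2))
  as.vector(peaks %*% profile$intensities)
}

# Maximum Pearson correlation between two curves over global shifts of
# -max_shift..max_shift grid points, correlating the overlapping windows.
shift_max_cor <- function(a, b, max_shift) {
  n <- length(a)
  best <- -1
  for (k in 0:max_shift) {
    i1 <- (1L + k):n
    i2 <- 1L:(n - k)
    best <- max(best,
                stats::cor(a[i1], b[i2]),
                stats::cor(a[i2], b[i1]))
  }
  best
}

#' Pairwise fingerprint similarity (curve-based Pearson)
#'
#' Similarity between two fingerprints is the Pearson correlation of their
#' Gaussian-smoothed densitometric curves, maximized over small global
#' shifts: `tolerance` sets the smoothing kernel width and `optimization`
#' the shift search range, both as fractions of the raster span.
#'
#' @param a,b [band_profile()] objects (filtered, non-empty).
#' @inheritParams rasterize_profile
#' @param optimization Shift search range as a fraction of the grid span.
#' @return Similarity in `[-1, 1]`; symmetric in its arguments;
#'   `profile_similarity(a, a)` is exactly 1.
#' @export
profile_similarity <- function(a, b, tolerance = 0.005, optimization = 0.005,
                               min_bp = 300, max_bp = 5000, n_grid = 1000L) {
  ca <- rasterize_profile(a, tolerance, min_bp, max_bp, n_grid)
  cb <- rasterize_profile(b, tolerance, min_bp, max_bp, n_grid)
  if (stats::sd(ca) == 0 || stats::sd(cb) == 0) {
    stop("degenerate (zero-variance) densitometric curve; similarity undefined")
  }
  if (identical(a$positions, b$positions) &&
      identical(a$intensities, b$intensities)) {
    return(1)
  }
  m <- max(0L, round(optimization * n_grid))
  min(1, max(-1, shift_max_cor(ca, cb, m)))
}

#' Full pairwise similarity matrix for a set of fingerprints
#'
#' Applies [filter_bands()] to every profile, drops strains left without
#' bands (with a warning), rasterizes the survivors once, and computes every
#' pairwise shift-optimized curve correlation.
#'
#' @param profiles List of [band_profile()] objects with unique strain ids.
#' @inheritParams profile_similarity
#' @return A symmetric numeric matrix with unit diagonal and strain ids as
#'   dimnames; class `c("similarity_matrix", "matrix")`.
#' @export
similarity_matrix <- function(profiles, tolerance = 0.005, optimization = 0.005,
                              min_bp = 300, max_bp = 5000, n_grid = 1000L) {
  stopifnot(is.list(profiles), length(profiles) >= 2L)
  ids <- unname(vapply(profiles, function(p) p$strain_id, character(1)))
  if (anyDuplicated(ids)) stop("duplicated strain ids")
  filtered <- lapply(profiles, filter_bands, min_bp = min_bp, max_bp = max_bp)
  keep <- !vapply(filtered, function(p) isTRUE(attr(p, "empty")), logical(1))
  filtered <- filtered[keep]
  ids <- ids[keep]
  n <- length(filtered)
  if (n < 2L) stop("fewer than two strains with in-window bands")

  curves <- vapply(filtered, rasterize_profile, numeric(n_grid),
                   tolerance = tolerance, min_bp = min_bp, max_bp = max_bp,
                   n_grid = n_grid)
  if (any(apply(curves, 2L, stats::sd) == 0)) {
    stop("degenerate (zero-variance) densitometric curve; similarity undefined")
  }
  m <- max(0L, round(optimization * n_grid))
  S <- stats::cor(curves)
  if (m > 0L) {
    for (k in 1:m) {
      M <- stats::cor(curves[(1L + k):n_grid, , drop = FALSE],
                      curves[1L:(n_grid - k), , drop = FALSE])
      S <- pmax(S, M, t(M))
    }
  }
  S <- (S + t(S)) / 2
  S[S > 1] <- 1
  S[S < -1] <- -1
  diag(S) <- 1
  dimnames(S) <- list(ids, ids)
  class(S) <- c("similarity_matrix", "matrix")
  S
}

validate_similarity <- function(S) {
  S <- unclass(as.matrix(S))
  stopifnot(is.numeric(S), nrow(S) == ncol(S))
  if (is.null(rownames(S))) {
    dimnames(S) <- list(as.character(seq_len(nrow(S))),
                        as.character(seq_len(nrow(S))))
  }
  if (max(abs(S - t(S))) > 1e-8) stop("similarity matrix is not symmetric")
  if (max(abs(diag(S) - 1)) > 1e-8) stop("similarity diagonal must be 1")
  if (any(S > 1 + 1e-8) || any(S < -1 - 1e-8)) {
    stop("similarity entries must lie in [-1, 1]")
  }
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}

#' UPGMA clustering of a similarity matrix
#'
#' Agglomerates strains on the dissimilarity `d = 1 - s` using size-weighted
#' arithmetic-average linkage. Ties in the minimal dissimilarity are broken
#' by merging the pair of clusters whose (smallest-label) identifiers are
#' lexicographically smallest, so the merge sequence is deterministic.
#'
#' @param S Similarity matrix (see [similarity_matrix()]).
#' @return An object of class `hclust` (method `"upgma"`); convert with
#'   [ape::as.phylo()] for Newick export. Merge heights are non-decreasing.
#' @export
upgma <- function(S) {
  S <- validate_similarity(S)
  n <- nrow(S)
  if (n < 2L) stop("UPGMA requires at least two strains")
  labels <- rownames(S)
  D <- 1 - S
  diag(D) <- NA_real_

  # active clusters: id in merge-matrix coding, size, smallest member label
  alive <- rep(TRUE, n)
  ids <- -seq_len(n)
  sizes <- rep(1L, n)
  minlab <- labels
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    idx <- which(upper.tri(D) & outer(alive, alive, "&"), arr.ind = TRUE)
    dvals <- D[idx]
    dmin <- min(dvals)
    cand <- idx[dvals == dmin, , drop = FALSE]
    # lexicographic tie-break on (smaller label, larger label) of the pair
    keys <- apply(cand, 1L, function(rc) {
      lab <- sort(c(minlab[rc[1L]], minlab[rc[2L]]))
      paste(lab, collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- min(pick); j <- max(pick)

    merge[step, ] <- sort(c(ids[i], ids[j]))
    height[step] <- dmin

    # Lance-Williams average-linkage update into slot i; retire slot j
    others <- which(alive); others <- others[!others %in% c(i, j)]
    D[i, others] <- (sizes[i] * D[i, others] + sizes[j] * D[j, others]) /
      (sizes[i] + sizes[j])
    D[others, i] <- D[i, others]
    alive[j] <- FALSE
    sizes[i] <- sizes[i] + sizes[j]
    ids[i] <- step
    minlab[i] <- min(minlab[i], minlab[j])
  }

  out <- list(merge = merge, height = height,
              order = hclust_leaf_order(merge),
              labels = labels, method = "upgma",
              call = match.call(), dist.method = "1 - similarity")
  class(out) <- "hclust"
  out
}

# Leaf ordering consistent with the merge matrix (left-to-right traversal).
hclust_leaf_order <- function(merge) {
  n <- nrow(merge) + 1L
  expand <- function(node) {
    if (node < 0L) return(-node)
    c(expand(merge[node, 1L]), expand(merge[node, 2L]))
  }
  expand(nrow(merge))
}

#' Deduplicate strains at a similarity threshold
#'
#' Forms single-linkage components over the graph whose edges join strain
#' pairs with similarity at or above `threshold`; strains below the
#' threshold to everything else are genomically distinct. One representative
#' (the lowest strain id) is kept per component.
#'
#' @param S Similarity matrix.
#' @param threshold Similarity at or above which two strains are considered
#'   the same genotype (default 0.90).
#' @return List with `representatives` (character, sorted), `membership`
#'   (named integer vector: component index per strain) and `n_components`.
#' @export
select_distinct <- function(S, threshold = 0.90) {
  S <- validate_similarity(S)
  n <- nrow(S)
  labels <- rownames(S)
  adj <- S >= threshold
  diag(adj) <- FALSE
  comp <- integer(n)
  k <- 0L
  for (v in seq_len(n)) {
    if (comp[v] == 0L) {
      k <- k + 1L
      queue <- v
      comp[v] <- k
      while (length(queue)) {
        u <- queue[[1L]]; queue <- queue[-1L]
        nb <- which(adj[u, ] & comp == 0L)
        comp[nb] <- k
        queue <- c(queue, nb)
      }
    }
  }
  reps <- vapply(seq_len(k), function(cc) min(labels[comp == cc]), character(1))
  names(comp) <- labels
  list(representatives = sort(reps), membership = comp, n_components = k)
}

#' Quadruplex marker profile for Clermont phylotyping
#'
#' @param arpA,chuA,yjaA,tspE4 Logical presence/absence of the quadruplex
#'   PCR markers arpA, chuA, yjaA and TspE4.C2.
#' @param group_c,group_e Optional confirmation screens, each one of
#'   `"untested"`, `"positive"`, `"negative"`.
#' @return An object of class `marker_profile`.
#' @export
marker_profile <- function(arpA, chuA, yjaA, tspE4,
                           group_c = "untested", group_e = "untested") {
  stopifnot(is.logical(arpA), is.logical(chuA), is.logical(yjaA),
            is.logical(tspE4), !anyNA(c(arpA, chuA, yjaA, tspE4)))
  group_c <- match.arg(group_c, c("untested", "positive", "negative"))
  group_e <- match.arg(group_e, c("untested", "positive", "negative"))
  structure(list(arpA = arpA, chuA = chuA, yjaA = yjaA, tspE4 = tspE4,
                 group_c = group_c, group_e = group_e),
            class = "marker_profile")
}

#' Assign a Clermont phylotype from quadruplex markers
#'
#' Deterministic lookup in the revised Clermont quadruplex decision table.
#' Genotypes that the quadruplex alone cannot resolve map to the composite
#' labels `"A/C"` and `"D/E"` unless the corresponding confirmation screen
#' was run. A confirmation screen reported positive for a group the
#' quadruplex genotype excludes is contradictory and yields `"unknown"`.
#'
#' @param m A [marker_profile()].
#' @return One of `"A"`, `"B1"`, `"B2"`, `"F"`, `"A/C"`, `"D/E"`, `"E"`,
#'   `"clade"`, `"unknown"`.
#' @export
assign_phylotype <- function(m) {
  stopifnot(inherits(m, "marker_profile"))
  g <- paste0(as.integer(m$arpA), as.integer(m$chuA),
              as.integer(m$yjaA), as.integer(m$tspE4))
  needs_c <- g == "1100"
  needs_e <- g %in% c("1101", "1110", "1111")
  if (!needs_c && m$group_c == "positive") return("unknown")
  if (!needs_e && m$group_e == "positive") return("unknown")
  switch(g,
    "1000" = "A",
    "1001" = "B1",
    "0100" = "F",
    "0110" = ,
    "0111" = ,
    "0101" = "B2",
    "1100" = switch(m$group_c,
                    positive = "A/C", untested = "A/C", negative = "A"),
    "1101" = ,
    "1110" = switch(m$group_e,
                    positive = "E", negative = "D/E", untested = "D/E"),
    "1111" = switch(m$group_e,
                    positive = "E", negative = "clade", untested = "unknown"),
    "0010" = "clade",
    "unknown"
  )
}
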