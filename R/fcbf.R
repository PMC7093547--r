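# Bootstrap-stabilised fast correlation-based filter (FCBF).
#
# Relevance and redundancy are both measured by symmetrical uncertainty
# on discretised variables; continuous features are binned by the
# Fayyad-Irani MDL criterion against the 4-class OSA severity coding of
# the reference AHI. One FCBF run selects relevant, non-redundant
# features; repeating it over bootstrap resamples of the training
# patients and thresholding each feature's selection count at the mean
# count stabilises the subset against the particular training sample.

entropy_counts <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Symmetrical uncertainty between two discretised variables
#'
#' `SU(X, Y) = 2 I(X; Y) / (H(X) + H(Y))`, computed with plug-in
#' (natural-log) entropies. Symmetric and bounded in \[0, 1\];
#' `SU(X, X) = 1` for non-constant `X` and 0 for independent variables.
#' When both variables are constant (`H(X) + H(Y) = 0`) the value is
#' defined as 0.
#'
#' @param x,y Equal-length vectors of discrete codes (factor, integer or
#'   character).
#' @return SU in \[0, 1\].
#' @export
symmetrical_uncertainty <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  joint <- table(x, y)
  hx <- entropy_counts(rowSums(joint))
  hy <- entropy_counts(colSums(joint))
  if (hx + hy == 0) return(0)
  hxy <- entropy_counts(as.vector(joint))
  mi <- hx + hy - hxy
  max(0, min(1, 2 * mi / (hx + hy)))
}

# Fayyad-Irani MDLP: recursive binary splitting of a continuous feature
# against a class label; a split is accepted only when its information
# gain exceeds the MDL cost. Returns the cut points (possibly none).
mdl_cuts <- function(x, y) {
  ord <- order(x)
  xs <- x[ord]
  ys <- as.integer(factor(y))
  ys <- ys[ord]
  k_all <- max(ys)
  onehot <- matrix(0L, length(ys), k_all)
  onehot[cbind(seq_along(ys), ys)] <- 1L
  cum <- apply(onehot, 2, cumsum)
  total <- cum[nrow(cum), , drop = TRUE]

  ent_bits <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log2(p))
  }

  recurse <- function(lo, hi) {
    n <- hi - lo + 1L
    if (n < 4L) return(numeric())
    cnt_hi <- cum[hi, ]
    cnt_lo <- if (lo > 1L) cum[lo - 1L, ] else rep(0L, k_all)
    cnt_all <- cnt_hi - cnt_lo
    ent_s <- ent_bits(cnt_all)
    if (ent_s == 0) return(numeric())
    # candidate splits: between adjacent distinct x values
    idx <- lo:(hi - 1L)
    cand <- idx[xs[idx] < xs[idx + 1L]]
    if (!length(cand)) return(numeric())
    left <- cum[cand, , drop = FALSE] -
      matrix(cnt_lo, length(cand), k_all, byrow = TRUE)
    right <- matrix(cnt_all, length(cand), k_all, byrow = TRUE) - left
    n_l <- rowSums(left)
    n_r <- rowSums(right)
    ent_row <- function(mat) {
      tot <- rowSums(mat)
      e <- numeric(nrow(mat))
      for (j in seq_len(ncol(mat))) {
        p <- mat[, j] / tot
        nz <- p > 0
        e[nz] <- e[nz] - p[nz] * log2(p[nz])
      }
      e
    }
    e_l <- ent_row(left)
    e_r <- ent_row(right)
    gain <- ent_s - (n_l * e_l + n_r * e_r) / n
    best <- which.max(gain)
    k1 <- rowSums(left > 0)[best]
    k2 <- rowSums(right > 0)[best]
    k <- sum(cnt_all > 0)
    delta <- log2(3^k - 2) - (k * ent_s - k1 * e_l[best] - k2 * e_r[best])
    if (gain[best] <= (log2(n - 1) + delta) / n) return(numeric())
    cut_idx <- cand[best]
    cut <- (xs[cut_idx] + xs[cut_idx + 1L]) / 2
    c(recurse(lo, cut_idx), cut, recurse(cut_idx + 1L, hi))
  }
  recurse(1L, length(xs))
}

#' Discretise features by the Fayyad-Irani MDL criterion
#'
#' @param table Data frame of numeric feature columns.
#' @param y Class labels driving the supervised binning.
#' @return Data frame of integer bin codes; a feature for which no cut
#'   point passes the MDL test collapses to a single bin (and thus has
#'   `SU = 0` with any target).
#' @export
mdl_discretise <- function(table, y) {
  as.data.frame(lapply(table, function(x) {
    cuts <- mdl_cuts(x, y)
    findInterval(x, cuts) + 1L
  }))
}

#' Fast correlation-based filter
#'
#' Ranks features by symmetrical uncertainty with the target
#' (descending, ties kept in canonical column order) and keeps a feature
#' only when no already-kept, more relevant feature is predominant over
#' it, i.e. when no kept `f_i` satisfies
#' `SU(f_i, f_j) >= SU(f_j, target)`.
#'
#' @param table Data frame of discretised feature columns.
#' @param target Discretised class vector.
#' @param delta Relevance floor; features with `SU(f, target) <= delta`
#'   never enter the ranking (default 0).
#' @return Character vector of selected feature names, most relevant
#'   first.
#' @export
fcbf <- function(table, target, delta = 0) {
  stopifnot(is.data.frame(table), ncol(table) >= 1L)
  su_rel <- vapply(table, symmetrical_uncertainty, numeric(1), y = target)
  keep <- which(su_rel > delta)
  if (!length(keep)) return(character())
  ord <- keep[order(-su_rel[keep], keep)]
  active <- rep(TRUE, length(ord))
  for (a in seq_along(ord)) {
    if (!active[a]) next
    fi <- table[[ord[a]]]
    for (b in seq_along(ord)) {
      if (b <= a || !active[b]) next
      if (symmetrical_uncertainty(fi, table[[ord[b]]]) >=
          su_rel[ord[b]]) {
        active[b] <- FALSE
      }
    }
  }
  names(table)[ord[active]]
}

#' Bootstrap-stabilised FCBF selection
#'
#' Repeats FCBF on `B` bootstrap resamples (patients resampled with
#' replacement; features rediscretised per replicate against the 4-class
#' severity coding of the resampled reference AHI). A feature's
#' significance is the number of replicates that selected it; features
#' whose count exceeds the mean count over the whole input feature set
#' are selected.
#'
#' @param table Feature table with a `reference_ahi` column (an `id`
#'   column, if present, is ignored).
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param delta Relevance floor passed to [fcbf()].
#' @return An object of class `selection_result`: `counts` (per
#'   feature), `threshold` (mean count), `selected` (feature names with
#'   count above threshold), `B`, `seed`, and `redrawn` (number of
#'   degenerate single-class resamples that were redrawn).
#' @export
bootstrap_fcbf <- function(table, B = 1000, seed = 1L, delta = 0) {
  stopifnot(B >= 1, "reference_ahi" %in% names(table))
  feats <- table[setdiff(names(table), c("id", "reference_ahi"))]
  y_all <- severity_of(table$reference_ahi)
  n <- nrow(feats)
  counts <- stats::setNames(integer(ncol(feats)), names(feats))
  redrawn <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(y_all[idx])) >= 2L) break
        redrawn <- redrawn + 1L
      }
      y <- droplevels(y_all[idx])
      disc <- mdl_discretise(feats[idx, , drop = FALSE], y)
      sel <- fcbf(disc, y, delta)
      counts[sel] <- counts[sel] + 1L
    }
  })
  structure(list(counts = counts, threshold = mean(counts),
                 selected = names(counts)[counts > mean(counts)],
                 B = B, seed = seed, redrawn = redrawn),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<FCBF bootstrap selection> B = %d, threshold = %.1f, %d/%d selected\n",
    x$B, x$threshold, length(x$selected), length(x$counts)))
  cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Export a selection result to JSON
#'
#' Serialises counts, threshold, selected set and seed, ready for
#' bar-chart rendering (counts per feature with a threshold line).
#'
#' @param sel A `selection_result`.
#' @param path Output path.
#' @export
write_selection <- function(sel, path) {
  jsonlite::write_json(
    list(counts = as.list(sel$counts), threshold = sel$threshold,
         selected = sel$selected, B = sel$B, seed = sel$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
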