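#' Discretize an expression matrix by per-feature median split
#'
#' The Fast Correlation-Based Filter operates on discrete variables. Each
#' feature is binarized at its across-sample median: code 1 if the value is
#' strictly above the median, 0 otherwise (ties go low). Constant features
#' are retained with a single code and flagged; their symmetrical
#' uncertainty with anything is 0 by convention.
#'
#' @param x An expression table with at least two samples.
#' @return A list of class `discretized_matrix` with `codes` (tibble:
#'   `feature_id` + integer 0/1 sample columns) and `split_rule` (tibble:
#'   `feature_id`, `threshold`, `degenerate`).
#' @export
discretize <- function(x) {
  m <- as_expr_matrix(x)
  if (ncol(m) < 2L) abort("discretization needs at least 2 samples.")
  med <- apply(m, 1L, stats::median)
  codes <- (m > med) * 1L
  storage.mode(codes) <- "integer"
  degenerate <- apply(codes, 1L, function(v) length(unique(v)) == 1L)
  structure(
    list(
      codes = expr_as_tibble(codes) |>
        dplyr::rename(feature_id = "gene_id"),
      split_rule = tibble(feature_id = rownames(m), threshold = med,
                          degenerate = degenerate)
    ),
    class = "discretized_matrix"
  )
}

# joint-count entropy helpers (plug-in estimator, bits, 0*log0 := 0)
entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Symmetrical uncertainty between two discrete vectors
#'
#' Computes plug-in (empirical-frequency) entropies in bits and the
#' normalized mutual information `SU(X, Y) = 2 I(X; Y) / (H(X) + H(Y))`,
#' which lies in \[0, 1\], equals 1 for identical non-constant vectors and
#' 0 under empirical independence. When `H(X) + H(Y) = 0` (both constant),
#' SU is 0 by convention.
#'
#' @param x,y Discrete vectors (integer, character or factor) of equal
#'   length >= 2.
#' @return A list with `su`, `mi`, `h_x`, `h_y` (all in bits except `su`).
#' @export
symmetrical_uncertainty <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have the same length.")
  if (length(x) < 2L) abort("need at least 2 observations.")
  joint <- table(x, y)
  h_x <- entropy_bits(rowSums(joint))
  h_y <- entropy_bits(colSums(joint))
  h_xy <- entropy_bits(as.vector(joint))
  mi <- max(h_x + h_y - h_xy, 0)
  su <- if (h_x + h_y > 0) 2 * mi / (h_x + h_y) else 0
  list(su = su, mi = mi, h_x = h_x, h_y = h_y)
}

# SU of every row of an integer 0/1 code matrix against a binary class
# vector; vectorized over features. Falls back to the generic routine for
# non-binary codes.
su_to_class_all <- function(codes, cls) {
  ids <- rownames(codes)
  y <- as.integer(factor(cls)) - 1L
  if (all(codes %in% c(0L, 1L)) && all(y %in% c(0L, 1L))) {
    n <- ncol(codes)
    n11 <- as.vector(codes %*% y)
    n10 <- rowSums(codes) - n11
    n01 <- sum(y) - n11
    n00 <- n - n11 - n10 - n01
    cnt <- cbind(n00, n01, n10, n11)
    h_xy <- apply(cnt, 1L, entropy_bits)
    h_x <- apply(cbind(n00 + n01, n10 + n11), 1L, entropy_bits)
    h_y <- entropy_bits(c(sum(y), n - sum(y)))
    mi <- pmax(h_x + h_y - h_xy, 0)
    su <- ifelse(h_x + h_y > 0, 2 * mi / (h_x + h_y), 0)
    stats::setNames(su, ids)
  } else {
    vapply(seq_len(nrow(codes)),
           function(i) symmetrical_uncertainty(codes[i, ], cls)$su,
           numeric(1L)) |> stats::setNames(ids)
  }
}

fcbf_codes_matrix <- function(disc) {
  stopifnot(inherits(disc, "discretized_matrix"))
  m <- as.matrix(disc$codes[, -1L, drop = FALSE])
  rownames(m) <- disc$codes$feature_id
  m
}

fcbf_result_tbl <- function(id, su, status, removed_by, delta) {
  out <- tibble(feature_id = id, su_to_class = su, status = status,
                removed_by = removed_by)
  attr(out, "delta") <- delta
  class(out) <- c("fcbf_result", class(out))
  out
}

#' Fast Correlation-Based Filter feature selection
#'
#' Two stages. Relevance: features whose symmetrical uncertainty with the
#' class is at least `delta` are kept, ordered by decreasing SU (ties by
#' feature id). Redundancy (predominance) removal: walking down that list,
#' the current feature is predominant and removes every later feature `q`
#' with `SU(predominant, q) >= SU(q, class)`; the walk continues with the
#' next surviving feature. The selected set are the predominant features in
#' list order.
#'
#' @param disc A `discretized_matrix` from [discretize()].
#' @param class_labels Discrete class vector (or data frame with
#'   `sample_id` + label column), at least two levels.
#' @param delta Relevance threshold on SU-to-class. Default 0.25.
#' @return A tibble of class `fcbf_result` with columns `feature_id`,
#'   `su_to_class`, `status` (`selected` / `removed` / `below_threshold`),
#'   `removed_by` (the predominant feature responsible, `NA` otherwise);
#'   selected features first, in selection order.
#' @export
fcbf_select <- function(disc, class_labels, delta = 0.25) {
  codes <- fcbf_codes_matrix(disc)
  cls <- align_labels(class_labels, colnames(codes))
  if (length(unique(cls)) < 2L) abort("class must have at least 2 levels.")
  su_c <- su_to_class_all(codes, cls)
  relevant <- names(su_c)[su_c >= delta]
  if (length(relevant) == 0L) {
    warn("no feature reaches the relevance threshold; empty selection")
    return(fcbf_result_tbl(names(su_c), unname(su_c), "below_threshold",
                           NA_character_, delta))
  }
  ord <- relevant[order(-su_c[relevant], relevant)]
  alive <- rep(TRUE, length(ord))
  removed_by <- stats::setNames(rep(NA_character_, length(ord)), ord)
  i <- 1L
  while (i <= length(ord)) {
    if (alive[i]) {
      p <- ord[i]
      j <- which(alive & seq_along(ord) > i)
      for (q_idx in j) {
        q <- ord[q_idx]
        su_pq <- symmetrical_uncertainty(codes[p, ], codes[q, ])$su
        if (su_pq >= su_c[[q]]) {
          alive[q_idx] <- FALSE
          removed_by[[q]] <- p
        }
      }
    }
    i <- i + 1L
  }
  sel <- ord[alive]
  rem <- ord[!alive]
  below <- setdiff(names(su_c), relevant)
  fcbf_result_tbl(
    id = c(sel, rem, below),
    su = unname(su_c[c(sel, rem, below)]),
    status = c(rep("selected", length(sel)), rep("removed", length(rem)),
               rep("below_threshold", length(below))),
    removed_by = c(rep(NA_character_, length(sel)), unname(removed_by[rem]),
                   rep(NA_character_, length(below))),
    delta = delta
  )
}

#' Reference FCBF implementation (test oracle)
#'
#' A direct, unoptimized transcription of the predominance definition: a
#' relevant feature is selected iff no other relevant feature with strictly
#' higher SU-to-class (or equal SU and smaller id) that is itself selected
#' makes it redundant. Evaluated by literal recursion over the ordered
#' relevance list, recomputing every pairwise SU on demand. Intended for
#' equivalence testing against [fcbf_select()], not for large inputs.
#'
#' @inheritParams fcbf_select
#' @return An `fcbf_result`, same contract as [fcbf_select()].
#' @export
fcbf_select_reference <- function(disc, class_labels, delta = 0.25) {
  codes <- fcbf_codes_matrix(disc)
  cls <- align_labels(class_labels, colnames(codes))
  if (length(unique(cls)) < 2L) abort("class must have at least 2 levels.")
  su_c <- vapply(rownames(codes),
                 function(f) symmetrical_uncertainty(codes[f, ], cls)$su,
                 numeric(1L))
  relevant <- names(su_c)[su_c >= delta]
  if (length(relevant) == 0L) {
    warn("no feature reaches the relevance threshold; empty selection")
    return(fcbf_result_tbl(names(su_c), unname(su_c), "below_threshold",
                           NA_character_, delta))
  }
  ord <- relevant[order(-su_c[relevant], relevant)]
  # linked-list walk: first element is predominant; scan all later
  # elements one at a time, deleting the redundant ones; then move to the
  # next remaining element and repeat.
  remaining <- ord
  selected <- character(0)
  removed <- character(0)
  removed_by <- character(0)
  while (length(remaining) > 0L) {
    p <- remaining[[1L]]
    selected <- c(selected, p)
    remaining <- remaining[-1L]
    keep <- logical(length(remaining))
    for (k in seq_along(remaining)) {
      q <- remaining[[k]]
      if (symmetrical_uncertainty(codes[p, ], codes[q, ])$su >= su_c[[q]]) {
        removed <- c(removed, q)
        removed_by <- c(removed_by, p)
        keep[k] <- FALSE
      } else {
        keep[k] <- TRUE
      }
    }
    remaining <- remaining[keep]
  }
  rem_order <- ord[ord %in% removed]
  below <- setdiff(names(su_c), relevant)
  fcbf_result_tbl(
    id = c(selected, rem_order, below),
    su = unname(su_c[c(selected, rem_order, below)]),
    status = c(rep("selected", length(selected)), rep("removed", length(rem_order)),
               rep("below_threshold", length(below))),
    removed_by = c(rep(NA_character_, length(selected)),
                   unname(stats::setNames(removed_by, removed)[rem_order]),
                   rep(NA_character_, length(below))),
    delta = delta
  )
}

#' Selected feature ids of an FCBF result
#'
#' @param result An `fcbf_result`.
#' @return Character vector of selected feature ids, in selection order.
#' @export
fcbf_selected <- function(result) {
  stopifnot(inherits(result, "fcbf_result"))
  result$feature_id[result$status == "selected"]
}
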