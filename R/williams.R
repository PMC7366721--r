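#' Angular similarity between two measurement vectors
#'
#' `1 - (2/pi) * arccos(cosine)` of the angle between the vectors: 1 for
#' parallel vectors, 0 for orthogonal, -1 for antiparallel. For
#' non-negative measurement vectors (as diameters are) the value lies in
#' \[0, 1\]. The cosine is clamped to \[-1, 1\] before the arccosine to
#' absorb floating-point overshoot.
#'
#' @param v_i,v_j Nonzero numeric vectors of equal length.
#' @return A single number in \[-1, 1\].
#' @export
#' @examples
#' angular_similarity(c(1, 2, 3), c(2, 4, 6))  # 1
#' angular_similarity(c(1, 0), c(0, 1))        # 0
angular_similarity <- function(v_i, v_j) {
  if (length(v_i) != length(v_j))
    abort("vectors must have equal length.",
          class = "orbitometry_validation_error")
  ni <- sqrt(sum(v_i^2)); nj <- sqrt(sum(v_j^2))
  if (ni == 0 || nj == 0)
    abort("angular similarity undefined for a zero vector.",
          class = "orbitometry_undefined_error")
  cosine <- sum(v_i * v_j) / (ni * nj)
  1 - (2 / pi) * acos(pmin(1, pmax(-1, cosine)))
}

#' Williams index of inter-rater agreement
#'
#' For each rater j, the ratio of j's average angular similarity to the
#' other raters over the other raters' average mutual similarity
#' (unordered pairs excluding j). An index of at least 1 means rater j
#' agrees with the group at least as well as the group agrees internally;
#' values just below 1 still indicate good agreement when all
#' similarities are near 1.
#'
#' @param rater_vectors The raters' measurement vectors: a numeric matrix
#'   with one column per rater (e.g. from [ratings_matrix()]) or a list
#'   of equal-length numeric vectors. At least 3 raters (the denominator
#'   needs two others).
#' @return An object of class `"williams_result"`: `similarity` (k x k
#'   symmetric matrix, unit diagonal) and `index` (named per-rater
#'   Williams index). [tidy()] gives a per-rater tibble.
#' @export
#' @examples
#' m <- ratings_matrix(
#'   simulate_measurements(fixture_truths(),
#'                         default_study_fixture()$graders,
#'                         study_design(seed = 7)),
#'   "virtual")
#' williams_index(m)$index
williams_index <- function(rater_vectors) {
  if (is.matrix(rater_vectors) || is.data.frame(rater_vectors)) {
    m <- as.matrix(rater_vectors)
    vecs <- lapply(seq_len(ncol(m)), function(j) m[, j])
    names(vecs) <- colnames(m) %||% paste0("rater", seq_len(ncol(m)))
  } else {
    vecs <- rater_vectors
    if (is.null(names(vecs))) names(vecs) <- paste0("rater", seq_along(vecs))
  }
  k <- length(vecs)
  if (k < 3L)
    abort("Williams index needs at least 3 raters.",
          class = "orbitometry_design_error")
  S <- diag(1, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    S[i, j] <- S[j, i] <- angular_similarity(vecs[[i]], vecs[[j]])
  }
  dimnames(S) <- list(names(vecs), names(vecs))
  idx <- vapply(seq_len(k), function(j) {
    others <- setdiff(seq_len(k), j)
    num <- mean(S[j, others])
    pairs <- utils::combn(others, 2)
    den <- mean(S[cbind(pairs[1, ], pairs[2, ])])
    if (den == 0)
      abort("Williams index undefined: zero within-group similarity.",
            class = "orbitometry_undefined_error")
    num / den
  }, numeric(1))
  names(idx) <- names(vecs)
  structure(list(similarity = S, index = idx), class = "williams_result")
}

#' @export
print.williams_result <- function(x, ...) {
  cat("Williams index per rater:\n")
  print(round(x$index, 4))
  invisible(x)
}

#' @describeIn williams_index Per-rater tibble (`rater`,
#'   `williams_index`).
#' @param x A `"williams_result"`.
#' @param ... Unused.
#' @export
tidy.williams_result <- function(x, ...) {
  tibble::tibble(rater = names(x$index), williams_index = unname(x$index))
}
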