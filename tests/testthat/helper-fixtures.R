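# Shared fixtures, built in code at test time.

.fixture_env <- new.env(parent = emptyenv())

# A compact phantom (60 mm cube at the CT spacing) reused across files.
test_phantom <- function() {
  if (is.null(.fixture_env$phantom)) {
    .fixture_env$phantom <- build_phantom(phantom_config(grid_shape = c(96, 96, 96)))
  }
  .fixture_env$phantom
}

# Default-condition simulated study (189 records).
test_study <- function(seed = 11L) {
  fx <- default_study_fixture(seed = seed)
  simulate_measurements(fx$truths, fx$graders, fx$design)
}

# Hand-built measurement table with constant per-cell values.
constant_table <- function(phys_vals, virt_vals, n_rep = 3L) {
  stopifnot(length(phys_vals) == 9L, length(virt_vals) == 9L)
  grid <- expand.grid(grader = c("P1", "P2", "V1", "V2"),
                      location_id = 1:9, repetition = seq_len(n_rep),
                      stringsAsFactors = FALSE)
  virt <- grepl("^V", grid$grader)
  tibble::tibble(
    grader_id = grid$grader,
    world = ifelse(virt, "virtual", "physical"),
    location_id = as.integer(grid$location_id),
    landmark_kind = ifelse(grid$location_id <= 6, "bead", "pin"),
    repetition = as.integer(grid$repetition),
    diameter_mm = ifelse(virt, virt_vals[grid$location_id],
                         phys_vals[grid$location_id]),
    refinements = ifelse(virt, 1L, NA_integer_)
  )
}

# Brute-force two-way ANOVA mean squares by explicit summation (oracle).
anova_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  gm <- sum(m) / (n * k)
  ssr <- 0; ssc <- 0; sst <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(m[i, ]) - gm)^2
  for (j in seq_len(k)) ssc <- ssc + n * (mean(m[, j]) - gm)^2
  for (i in seq_len(n)) for (j in seq_len(k)) sst <- sst + (m[i, j] - gm)^2
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = (sst - ssr - ssc) / ((n - 1) * (k - 1)),
       ssr = ssr, ssc = ssc, sse = sst - ssr - ssc, sst = sst)
}

# Brute-force Williams index by explicit double loops (oracle).
williams_oracle <- function(vecs) {
  k <- length(vecs)
  s <- function(a, b) {
    cosv <- sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
    1 - 2 / pi * acos(max(-1, min(1, cosv)))
  }
  sapply(seq_len(k), function(j) {
    num <- 0; nn <- 0
    for (i in seq_len(k)) if (i != j) { num <- num + s(vecs[[j]], vecs[[i]]); nn <- nn + 1 }
    den <- 0; nd <- 0
    for (i in seq_len(k - 1)) for (l in (i + 1):k)
      if (i != j && l != j) { den <- den + s(vecs[[i]], vecs[[l]]); nd <- nd + 1 }
    (num / nn) / (den / nd)
  })
}
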