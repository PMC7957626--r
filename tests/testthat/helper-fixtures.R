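# Shared fixtures, built lazily and cached so expensive objects (a small
# trained study) are constructed once per test run.

fixture_env <- new.env(parent = emptyenv())

# A compact end-to-end study: synthetic dataset, 16-channel backbone, trained
# {P3,P6,P7} head. Used by the head, saliency, degradation and CLI tests.
small_study <- function() {
  if (is.null(fixture_env$study)) {
    man <- generate_dataset(c(73, 30), seed = 420L)
    bb <- make_test_backbone(7L, channels = 16L)
    tr <- manifest_split(man, "train")
    te <- manifest_split(man, "test")
    head <- train_head(
      head_config(c("P3", "P6", "P7"), seed = 420L, epochs = 8000L),
      tr, bb
    )
    fixture_env$study <- list(manifest = man, backbone = bb,
                              train = tr, test = te, head = head)
  }
  fixture_env$study
}

# Random GAP+FC head over K channels with C classes.
random_head <- function(K, C = 2L, grid = c(8L, 8L), sd = 1,
                        levels = c("P3", "P6", "P7")) {
  classifier_head(matrix(rnorm(K * C, sd = sd), K, C), rnorm(C),
                  levels, grid)
}

# Random positive-ish feature block.
random_block <- function(grid, K) {
  array(rnorm(prod(grid) * K, mean = 0.5, sd = 1), c(grid, K))
}

# Largest connected component count of a binary mask (4-connectivity).
n_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    while (length(queue) > 0L) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (cur - 1L) %% nrow(mask) + 1L
      cc <- (cur - 1L) %/% nrow(mask) + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1]; c2 <- cc + d[2]
        if (rr >= 1L && rr <= nrow(mask) && c2 >= 1L && c2 <= ncol(mask)) {
          idx <- (c2 - 1L) * nrow(mask) + rr
          if (mask[idx] && lab[idx] == 0L) {
            lab[idx] <- comp
            queue <- c(queue, idx)
          }
        }
      }
    }
  }
  comp
}
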