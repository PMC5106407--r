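## Shared fixtures, built in code at test time.

## deterministic random grey image
rand_gray <- function(h, w, seed = 1) {
  set.seed(seed)
  matrix(as.numeric(sample(0:255, h * w, replace = TRUE)), h, w)
}

## deterministic random RGB image
rand_rgb <- function(h, w, seed = 1) {
  set.seed(seed)
  array(as.numeric(sample(0:255, h * w * 3, replace = TRUE)),
        dim = c(h, w, 3))
}

## plain flat image with a bright disc planted at (row0, col0) (0-based)
planted_disc_image <- function(h, w, row0, col0, radius,
                               bg = 100, value = 220) {
  img <- matrix(bg, h, w)
  rr <- row(img) - 1; cc <- col(img) - 1
  img[(rr - row0)^2 + (cc - col0)^2 <= radius^2] <- value
  img
}

## independent R-level flood fill labelling oracle (8-connectivity)
flood_label_oracle <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii >= 1 && ii <= h && jj >= 1 && jj <= w &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- nxt
          queue[[length(queue) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

## grading table reproducing the three-expert count table
expert_table <- function() expand_grading_counts(expert_grading_counts())

## consensus stage vector (one entry per image)
consensus_stages <- function() {
  cons <- consensus_grading_counts()
  rep(names(cons), cons)
}
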