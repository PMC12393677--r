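# Small fixtures built in code, shared across test files.

toy_taxonomy <- function() {
  make_taxonomy(
    c("Lactobacillus crispatus", "Lactobacillus iners", "Lactobacillus jensenii",
      "Gardnerella vaginalis", "Prevotella bivia", "Fannyhessea vaginae"),
    c("Lactobacillus", "Lactobacillus", "Lactobacillus",
      "Gardnerella", "Prevotella", "Fannyhessea")
  )
}

# deterministic small count matrix over the toy taxonomy
toy_counts <- function(seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rpois(8 * 6, 40), nrow = 8,
                dimnames = list(paste0("s", 1:8), toy_taxonomy()$species))
    m
  })
}

# standalone NIPALS PLS2 oracle, independent of the package implementation:
# textbook algorithm, used to cross-check single-block fits and
# residualization.
oracle_pls2 <- function(x, y, a) {
  x <- scale(x, center = TRUE, scale = FALSE)
  y <- scale(y, center = TRUE, scale = FALSE)
  n <- nrow(x)
  scores <- matrix(0, n, a)
  preds <- matrix(0, nrow(y), ncol(y))
  for (h in seq_len(a)) {
    u <- y[, 1, drop = FALSE]
    repeat {
      w <- crossprod(x, u); w <- w / sqrt(sum(w^2))
      t_ <- x %*% w
      q <- crossprod(y, t_) / sum(t_^2)
      u_new <- y %*% q / sum(q^2)
      if (sum((u_new - u)^2) < 1e-12 * sum(u_new^2)) break
      u <- u_new
    }
    p <- crossprod(x, t_) / sum(t_^2)
    q <- crossprod(y, t_) / sum(t_^2)
    preds <- preds + t_ %*% t(q)
    x <- x - t_ %*% t(p)
    y <- y - t_ %*% t(q)
    scores[, h] <- t_
  }
  list(scores = scores, predictions = preds, residuals = y)
}
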