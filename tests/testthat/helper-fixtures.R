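# Shared fixtures, all built in code at test time.

# Tiny profile with known values.
toy_profile <- function() {
  abundance_profile(matrix(c(0.5, 0.3, 0.2,
                             0.1, 0.1, 0.8), 2L, 3L, byrow = TRUE),
                    sample_ids = c("s1", "s2"),
                    feature_ids = c("fA", "fB", "fC"))
}

# Linearly separable two-feature cohort.
separable_data <- function(n = 20L, seed = 1L) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2L)
  X <- cbind(rnorm(n, mean = ifelse(y == 1, 3, -3), sd = 0.5),
             rnorm(n, mean = ifelse(y == 1, 3, -3), sd = 0.5))
  colnames(X) <- c("x1", "x2")
  list(X = X, y = y)
}

# XOR-patterned labels: only a nonlinear decision boundary separates them.
xor_data <- function(n = 400L, flip = 0.05, seed = 11L) {
  set.seed(seed)
  x1 <- runif(n, -1, 1); x2 <- runif(n, -1, 1)
  y <- as.integer(x1 * x2 > 0)
  fl <- sample.int(n, round(flip * n))
  y[fl] <- 1L - y[fl]
  list(X = cbind(x1 = x1, x2 = x2), y = y)
}

# Ten-node DAG with eight strong edges, for network recovery.
planted_dag <- function() {
  data.frame(source = c(1L, 1L, 2L, 3L, 4L, 5L, 6L, 7L),
             target = c(2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L),
             coef = 1)
}

# Brute-force pairwise-concordance AUC (the independent oracle).
pairwise_auc <- function(labels, scores) {
  cs <- scores[labels == 1]
  ct <- scores[labels == 0]
  tot <- 0
  for (a in cs) tot <- tot + sum(a > ct) + 0.5 * sum(a == ct)
  tot / (length(cs) * length(ct))
}
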