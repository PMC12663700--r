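# Independent brute-force oracles and small fixture builders. Each oracle
# is written from the definition, in a deliberately different style from
# the package implementation, so the two can disagree.

# Jensen-Shannon distance by direct term-by-term summation.
oracle_js <- function(p, q) {
  m <- (p + q) / 2
  acc <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) acc <- acc + 0.5 * p[i] * (log(p[i]) - log(m[i])) / log(2)
    if (q[i] > 0) acc <- acc + 0.5 * q[i] * (log(q[i]) - log(m[i])) / log(2)
  }
  sqrt(acc)
}

# Naive O(m^2) LOF with explicit loops (tie-inclusive neighbourhoods).
oracle_lof <- function(points, k) {
  points <- as.matrix(points)
  m <- nrow(points)
  k <- min(k, m - 1)
  d <- function(i, j) sqrt(sum((points[i, ] - points[j, ])^2))
  kdist <- numeric(m)
  nbr <- vector("list", m)
  for (i in 1:m) {
    di <- sapply(setdiff(1:m, i), function(j) d(i, j))
    kdist[i] <- sort(di)[k]
    nbr[[i]] <- setdiff(1:m, i)[di <= kdist[i]]
  }
  lrd <- numeric(m)
  for (i in 1:m) {
    reach <- sapply(nbr[[i]], function(j) max(kdist[j], d(i, j)))
    lrd[i] <- 1 / max(mean(reach), 1e-12)
  }
  sapply(1:m, function(i) mean(sapply(nbr[[i]], function(j) lrd[j])) / lrd[i])
}

# Correspondence analysis of an indicator matrix by direct
# eigen-decomposition of S'S (no SVD), returning row principal
# coordinates for the leading axes.
oracle_ca_rows <- function(cat_df, k) {
  cat_df <- as.data.frame(cat_df, stringsAsFactors = FALSE)
  n <- nrow(cat_df)
  Z <- NULL
  for (nm in names(cat_df)) {
    f <- factor(cat_df[[nm]])
    blk <- sapply(levels(f), function(l) as.numeric(cat_df[[nm]] == l))
    Z <- cbind(Z, blk)
  }
  P <- Z / sum(Z)
  r <- rowSums(P); cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - r %o% cc) %*% diag(1 / sqrt(cc))
  eg <- eigen(t(S) %*% S, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  keep <- which(lam > max(lam) * 1e-10)[seq_len(k)]
  # row principal coords: Dr^-1/2 S v  (per axis; no scaling by sigma
  # needed since S v = sigma u and F = Dr^-1/2 u sigma = Dr^-1/2 S v)
  F <- diag(1 / sqrt(r)) %*% S %*% eg$vectors[, keep, drop = FALSE]
  list(rows = F, lambdas = lam)
}

# Align axis signs of two score matrices before comparing (axis direction
# is arbitrary in any spectral method).
align_signs <- function(ref, x) {
  for (a in seq_len(ncol(x))) {
    if (sum(ref[, a] * x[, a]) < 0) x[, a] <- -x[, a]
  }
  x
}

# Random probability vector on nb bins (Dirichlet via gammas).
random_density <- function(nb) {
  g <- rgamma(nb, shape = 0.5)
  g / sum(g)
}

# Small mixed-type codebook used across tests.
toy_codebook <- function() {
  codebook(list(
    variable_spec("Q1", "s1", "categorical", c("no", "yes")),
    variable_spec("Q2", "s1", "continuous",
                  branch = list(parent = "Q1", values = "yes")),
    variable_spec("Q3", "s1", "text"),
    variable_spec("Q4", "s2", "ordinal", c("never", "sometimes", "often")),
    variable_spec("Q5", "s2", "multichoice"),
    variable_spec("Q6", "s2", "continuous")))
}

toy_dataset <- function() {
  df <- data.frame(
    site = c("A", "A", "B", "B"),
    Q1 = c("yes", "no", "yes", NA),
    Q2 = c("1.5", NA, "2.5", NA),
    Q3 = c("hello", "world", NA, "txt"),
    Q4 = c("never", "often", NA, "sometimes"),
    Q5 = c("a;b", "c", "a", NA),
    Q6 = c("0.1", "0.2", "0.3", "0.4"),
    stringsAsFactors = FALSE)
  msv_dataset(df, toy_codebook())
}

# Encoded matrix straight from numbers (bypasses codebook plumbing).
encoded_from_matrix <- function(V, site = rep("A", nrow(V)),
                                vtype = rep("continuous", ncol(V))) {
  colnames(V) <- colnames(V) %||% paste0("V", seq_len(ncol(V)))
  structure(list(
    values = V, mask = is.na(V),
    columns = data.frame(id = colnames(V), vtype = vtype,
                         n_levels = ifelse(vtype == "continuous", 0L, 4L),
                         section = "s1", stringsAsFactors = FALSE),
    site = site,
    levels = rep(list(character()), ncol(V))),
    class = "encoded_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
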