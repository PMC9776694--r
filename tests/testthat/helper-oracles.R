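# Independent naive implementations of the stepwise outranking and
# closeness computations, used as oracles. Deliberately written as plain
# loops over the defining equations, sharing no code with the package.

# Hard-coded linguistic centroids (triangle centroid = mean of vertices).
oracle_centroid <- c(VL = (0 + 0 + 0.25) / 3,
                     L  = (0 + 0.25 + 0.50) / 3,
                     M  = (0.25 + 0.50 + 0.75) / 3,
                     H  = (0.50 + 0.75 + 1) / 3,
                     VH = (0.75 + 1 + 1) / 3)

# Defuzzify a matrix-like data frame (alternative column + cells that are
# numbers or labels) into a plain numeric matrix.
oracle_defuzzify <- function(df) {
  X <- sapply(df[-1], function(col) {
    sapply(col, function(cell) {
      num <- suppressWarnings(as.numeric(cell))
      if (!is.na(num)) num else unname(oracle_centroid[toupper(cell)])
    })
  })
  X <- matrix(as.numeric(X), nrow = nrow(df),
              dimnames = list(df$alternative, names(df)[-1]))
  X
}

oracle_weights <- function(labels) {
  w <- unname(oracle_centroid[labels])
  w / sum(w)
}

# Population standard deviation per column after cost-direction sign flip.
oracle_auto_s <- function(X, directions) {
  sapply(seq_len(ncol(X)), function(k) {
    x <- X[, k]
    sqrt(mean((x - mean(x))^2))
  })
}

naive_promethee <- function(X, w, s, directions) {
  n <- nrow(X); K <- ncol(X)
  p <- function(d, sk) if (d <= 0) 0 else 1 - exp(-d^2 / (2 * sk^2))
  pi_mat <- matrix(0, n, n)
  for (t in seq_len(n)) {
    for (tp in seq_len(n)) {
      if (t == tp) next
      acc <- 0
      for (k in seq_len(K)) {
        d <- X[t, k] - X[tp, k]
        if (directions[k] == "cost") d <- -d
        if (s[k] > 0) acc <- acc + w[k] * p(d, s[k])
      }
      pi_mat[t, tp] <- acc
    }
  }
  phi_plus <- numeric(n); phi_minus <- numeric(n)
  for (t in seq_len(n)) {
    phi_plus[t] <- sum(pi_mat[t, -t]) / (n - 1)
    phi_minus[t] <- sum(pi_mat[-t, t]) / (n - 1)
  }
  list(pi = pi_mat, phi_plus = phi_plus, phi_minus = phi_minus,
       phi_net = phi_plus - phi_minus)
}

naive_topsis <- function(X, w, directions) {
  m <- nrow(X); n <- ncol(X)
  N <- X
  for (j in seq_len(n)) N[, j] <- X[, j] / sqrt(sum(X[, j]^2))
  V <- N
  for (j in seq_len(n)) V[, j] <- w[j] * N[, j]
  a_plus <- numeric(n); a_minus <- numeric(n)
  for (j in seq_len(n)) {
    if (directions[j] == "benefit") {
      a_plus[j] <- max(V[, j]); a_minus[j] <- min(V[, j])
    } else {
      a_plus[j] <- min(V[, j]); a_minus[j] <- max(V[, j])
    }
  }
  d_plus <- numeric(m); d_minus <- numeric(m)
  for (i in seq_len(m)) {
    d_plus[i] <- sqrt(sum((V[i, ] - a_plus)^2))
    d_minus[i] <- sqrt(sum((V[i, ] - a_minus)^2))
  }
  list(d_plus = d_plus, d_minus = d_minus,
       closeness = d_minus / (d_minus + d_plus))
}

# Small builders shared across tests ---------------------------------------

crit_tbl <- function(names, directions = "benefit", labels = "H",
                     s = NA_real_) {
  tibble::tibble(
    criterion = names,
    direction = rep_len(directions, length(names)),
    weight_label = rep_len(labels, length(names)),
    preference_s = rep_len(s, length(names))
  )
}

random_crisp_matrix <- function(n_alt, criteria, seed) {
  set.seed(seed)
  cells <- matrix(runif(n_alt * nrow(criteria), 0, 100), n_alt)
  out <- tibble::as_tibble(as.data.frame(cells))
  names(out) <- criteria$criterion
  dplyr::bind_cols(
    tibble::tibble(alternative = paste0("a", seq_len(n_alt))), out)
}

random_criteria <- function(k, seed) {
  set.seed(seed)
  crit_tbl(paste0("c", seq_len(k)),
           directions = sample(c("benefit", "cost"), k, replace = TRUE),
           labels = sample(c("VL", "L", "M", "H", "VH"), k, replace = TRUE))
}
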