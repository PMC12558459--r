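# Independent brute-force oracles. Written deliberately naively, with no code
# shared with the package implementation, so tests compare two routes.

# Exact signed-rank p by enumerating every sign assignment with expand.grid.
oracle_wilcoxon_p <- function(x, y, alternative) {
  d <- (x - y)[x != y]
  n <- length(d)
  rk <- rank(abs(d))
  W_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- signs %*% rk
  mu <- sum(rk) / 2
  eps <- 1e-9
  switch(alternative,
         greater = mean(Ws >= W_obs - eps),
         less = mean(Ws <= W_obs + eps),
         two_sided = mean(abs(Ws - mu) >= abs(W_obs - mu) - eps))
}

# Exact Mann-Whitney p by enumerating every assignment of pooled values to
# group 1, recomputing U from scratch per assignment.
oracle_mann_whitney_p <- function(a, b, alternative) {
  pooled <- c(a, b)
  n1 <- length(a)
  rk <- rank(pooled)
  U_of <- function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2
  U_obs <- U_of(seq_len(n1))
  mu <- n1 * length(b) / 2
  eps <- 1e-9
  Us <- apply(utils::combn(length(pooled), n1), 2, U_of)
  switch(alternative,
         greater = mean(Us >= U_obs - eps),
         less = mean(Us <= U_obs + eps),
         two_sided = mean(abs(Us - mu) >= abs(U_obs - mu) - eps))
}

# Exhaustive-search CART oracle: at each node try every feature and every
# midpoint threshold, score by Gini decrease with the same acceptance gates,
# and return the nested structure for comparison against fit_cart.
oracle_gini <- function(y) {
  tab <- table(factor(y, levels = c("no_neglect", "neglect")))
  1 - sum((tab / sum(tab))^2)
}

oracle_cart <- function(data, labels, minsplit, minbucket, cp) {
  root_misclass <- max(min(table(factor(labels,
                                        levels = c("no_neglect", "neglect")))), 1)
  build <- function(df, y) {
    tab <- table(factor(y, levels = c("no_neglect", "neglect")))
    maj <- if (tab[["neglect"]] > tab[["no_neglect"]]) "neglect" else "no_neglect"
    leaf <- list(type = "leaf", class = maj)
    if (length(y) < minsplit || min(tab) == 0) return(leaf)
    best_dec <- -Inf; best_feat <- NULL; best_thr <- NULL
    for (feat in sort(names(df))) {
      vals <- sort(unique(df[[feat]]))
      if (length(vals) < 2) next
      for (j in seq_len(length(vals) - 1)) {
        thr <- (vals[j] + vals[j + 1]) / 2
        li <- df[[feat]] < thr
        if (sum(li) < minbucket || sum(!li) < minbucket) next
        dec <- oracle_gini(y) -
          sum(li) / length(y) * oracle_gini(y[li]) -
          sum(!li) / length(y) * oracle_gini(y[!li])
        if (dec > best_dec + 1e-12) {
          best_dec <- dec; best_feat <- feat; best_thr <- thr
        }
      }
    }
    if (is.null(best_feat)) return(leaf)
    li <- df[[best_feat]] < best_thr
    misclass <- function(yy) {
      t2 <- table(factor(yy, levels = c("no_neglect", "neglect")))
      sum(t2) - max(t2)
    }
    improvement <- misclass(y) - misclass(y[li]) - misclass(y[!li])
    if (improvement < cp * root_misclass - 1e-12) return(leaf)
    list(type = "split", feature = best_feat, threshold = best_thr,
         left = build(df[li, , drop = FALSE], y[li]),
         right = build(df[!li, , drop = FALSE], y[!li]))
  }
  build(data, as.character(labels))
}

# Strip a keen_cart tree down to the fields the oracle produces.
skeleton <- function(node) {
  if (node$type == "leaf") return(list(type = "leaf", class = node$class))
  list(type = "split", feature = node$feature, threshold = node$threshold,
       left = skeleton(node$left), right = skeleton(node$right))
}
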