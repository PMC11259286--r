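# shared fixtures and independent oracles

toy_statements <- function(n = 4) {
  new_statements(data.frame(statement_id = seq_len(n),
                            text = sprintf("statement %d", seq_len(n))))
}

# sorter's partition given as a list of id vectors, optionally labeled
toy_sort <- function(sorter_id, piles, labels = NULL) {
  if (is.null(labels)) labels <- sprintf("pile %d", seq_along(piles))
  new_sort(sorter_id, Map(function(m, l) list(label = l, members = m),
                          piles, labels))
}

as_sorts <- function(...) structure(list(...), class = "cm_sorts")

# the three-sorter toy over 4 statements used throughout the similarity tests
toy_three_sorters <- function() {
  as_sorts(toy_sort("A", list(c(1, 2), c(3, 4))),
           toy_sort("B", list(c(1, 2, 3), 4)),
           toy_sort("C", list(1, c(2, 3), 4)))
}

# brute-force Ward agglomeration: recompute delta-ESS over all cluster pairs
# at every step; returns merge costs and the partition after each merge
brute_ward <- function(X) {
  ess <- function(M) if (nrow(M) < 2) 0 else sum(scale(M, scale = FALSE)^2)
  cl <- as.list(seq_len(nrow(X)))
  costs <- numeric()
  partitions <- list()
  while (length(cl) > 1) {
    bestd <- Inf; best <- NULL
    for (i in seq_along(cl)) for (j in seq_along(cl)) if (i < j) {
      d <- ess(X[c(cl[[i]], cl[[j]]), , drop = FALSE]) -
        ess(X[cl[[i]], , drop = FALSE]) - ess(X[cl[[j]], , drop = FALSE])
      if (d < bestd - 1e-12) { bestd <- d; best <- c(i, j) }
    }
    cl[[best[1]]] <- c(cl[[best[1]]], cl[[best[2]]])
    cl[[best[2]]] <- NULL
    costs <- c(costs, bestd)
    part <- integer(nrow(X))
    for (g in seq_along(cl)) part[cl[[g]]] <- g
    partitions[[length(partitions) + 1L]] <- part
  }
  list(costs = costs, partitions = partitions)
}

# brute-force ARI: count agreeing pairs directly over all C(n,2) pairs
brute_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (!sa && !sb) s00 <- s00 + 1
    else if (sa) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  npairs <- n * (n - 1) / 2
  expected <- (s11 + s10) * (s11 + s01) / npairs
  denom <- ((s11 + s10) + (s11 + s01)) / 2 - expected
  if (denom == 0) return(1)
  (s11 - expected) / denom
}

# normalized view of a sort record for order-independent comparison
normalize_sort <- function(s) {
  piles <- lapply(s$piles, function(p) list(label = p$label,
                                            members = sort(p$members)))
  keys <- vapply(piles, function(p)
    paste(p$label, paste(p$members, collapse = ","), sep = "|"), "")
  list(sorter_id = s$sorter_id, piles = piles[order(keys)])
}

random_rigid_transform <- function(X, scale = FALSE) {
  theta <- runif(1, 0, 2 * pi)
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  if (runif(1) < 0.5) R[, 2] <- -R[, 2]          # reflection
  s <- if (scale) exp(runif(1, -1, 1)) else 1
  sweep(s * (X %*% R), 2, rnorm(2), `+`)
}
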