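# Independent oracles, spelled out from first principles so they share no
# code path with the implementation.

# Saturating rescale: sort, take the (k+1)-th order statistics from each
# end, clip, map affinely.
oracle_saturate <- function(v, frac, out_max = 255) {
  n <- length(v)
  k <- floor(frac * n)
  s <- sort(v)
  L <- s[k + 1]
  H <- s[n - k]
  w <- v
  w[w < L] <- L
  w[w > H] <- H
  (w - L) / (H - L) * out_max
}

# Connected components via igraph on the pixel adjacency graph.
oracle_components <- function(mask, connectivity) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  if (length(fg) == 0) return(list())
  id <- match(seq_len(nr * nc), fg)  # linear index -> vertex id
  offs <- list(c(1, 0), c(0, 1))
  if (connectivity == 8) offs <- c(offs, list(c(1, 1), c(1, -1)))
  edges <- NULL
  r <- (fg - 1) %% nr + 1
  c <- (fg - 1) %/% nr + 1
  for (o in offs) {
    r2 <- r + o[1]; c2 <- c + o[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    nb <- (c2[ok] - 1) * nr + r2[ok]
    keep <- mask[nb]
    edges <- rbind(edges, cbind(id[fg[ok][keep]], id[nb[keep]]))
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  mem <- igraph::components(g)$membership
  lapply(split(fg, mem), function(idx)
    cbind(row = (idx - 1) %% nr + 1, col = (idx - 1) %/% nr + 1))
}

# Canonical form of a component partition: sorted list of sorted linear
# index vectors, so two labelings compare as set partitions.
canonical_partition <- function(comps, nr) {
  sets <- unname(lapply(comps, function(p) unname(sort((p[, 2] - 1) * nr + p[, 1]))))
  sets[order(vapply(sets, min, numeric(1)))]
}

# Closed-form simple OLS with t-based interval and p-value.
oracle_ols <- function(x, y, level = 0.95) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  rss <- sum((y - intercept - slope * x)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  tq <- qt(1 - (1 - level) / 2, n - 2)
  tstat <- slope / se
  list(slope = slope, intercept = intercept, se = se,
       ci = c(slope - tq * se, slope + tq * se),
       p = 2 * pt(-abs(tstat), n - 2))
}

# A small easy-regime phantom spec with a lacune confound.
easy_spec <- function(n_pvs, seed, ...) {
  synthetic_spec(n_pvs = n_pvs,
                 lacunes = list(n = 1, diameter_mm = 5, peak_fraction = 0.95),
                 seed = seed, ...)
}
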