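# Independent oracles, deliberately naive implementations.

# Ray-casting (crossing-number) point-in-polygon, independent of the
# package's containment path.
ray_cast_inside <- function(pts, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Brute-force DBSCAN with the package's deterministic tie rules:
# clusters are connected components of core points, numbered by their
# smallest core index; border points take the lowest cluster id among
# their core neighbours.
dbscan_oracle <- function(pts, eps, min_samples) {
  n <- nrow(pts)
  if (n == 0) return(integer(0))
  d <- as.matrix(stats::dist(pts)) <= eps
  is_core <- rowSums(d) >= min_samples  # diagonal TRUE counts the point itself
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is_core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    comp <- i
    repeat {
      grow <- which(is_core & labels == 0L &
                      apply(d[, comp, drop = FALSE], 1, any))
      grow <- setdiff(grow, comp)
      labels[comp] <- cl
      if (!length(grow)) break
      comp <- c(comp, grow)
    }
  }
  for (i in which(!is_core)) {
    core_nb <- which(d[i, ] & is_core)
    if (length(core_nb)) labels[i] <- min(labels[core_nb])
  }
  labels
}
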