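# Independent oracles used to validate the implementation paths.

# Brute-force single-source shortest path by repeated edge relaxation
# (Bellman-Ford). friction: matrix of s/m with NA impassable; origin:
# column-major pixel index. Returns minutes, NA where unreachable.
bf_travel_time <- function(friction, pixel_size, origin) {
  nr <- nrow(friction); nc <- ncol(friction)
  n <- nr * nc
  dist <- rep(Inf, n)
  pass <- !is.na(friction)
  stopifnot(pass[origin])
  dist[origin] <- 0
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  repeat {
    changed <- FALSE
    for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
      a <- (c0 - 1L) * nr + r0
      if (!pass[a] || !is.finite(dist[a])) next
      for (k in seq_len(nrow(offs))) {
        r1 <- r0 + offs$dr[k]; c1 <- c0 + offs$dc[k]
        if (r1 < 1 || r1 > nr || c1 < 1 || c1 > nc) next
        b <- (c1 - 1L) * nr + r1
        if (!pass[b]) next
        d <- pixel_size * if (offs$dr[k] != 0 && offs$dc[k] != 0) sqrt(2) else 1
        w <- d * (friction[a] + friction[b]) / 2
        if (dist[a] + w < dist[b] - 1e-12) {
          dist[b] <- dist[a] + w
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  out <- dist / 60
  out[is.infinite(out)] <- NA
  matrix(out, nr)
}

# Exact two-sided Fisher p for a small r x c table by full enumeration
# of tables with the observed margins (point-probability rule).
enum_fisher_p <- function(tab) {
  tab <- as.matrix(tab)
  rs <- rowSums(tab); cs <- colSums(tab)
  log_prob <- function(m) {
    sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(sum(m) + 1) -
      sum(lgamma(m + 1))
  }
  tables <- list()
  gen <- function(partial, row) {
    if (row == length(rs)) {
      rem <- cs - colSums(do.call(rbind, partial))
      if (all(rem >= 0)) tables[[length(tables) + 1L]] <<-
          do.call(rbind, c(partial, list(rem)))
      return(invisible())
    }
    rem_cols <- cs - if (length(partial))
      colSums(do.call(rbind, partial)) else rep(0, length(cs))
    fill_row <- function(prefix, j) {
      if (j == length(cs)) {
        last <- rs[row] - sum(prefix)
        if (last >= 0 && last <= rem_cols[length(cs)])
          gen(c(partial, list(c(prefix, last))), row + 1L)
        return(invisible())
      }
      for (v in 0:min(rs[row] - sum(prefix), rem_cols[j]))
        fill_row(c(prefix, v), j + 1L)
    }
    fill_row(numeric(0), 1L)
  }
  gen(list(), 1L)
  lp_obs <- log_prob(tab)
  lps <- vapply(tables, log_prob, 0)
  sum(exp(lps[lps <= lp_obs + 1e-7]))
}

# Wrap a bare friction matrix (s/m, NA impassable) as a
# friction_surface for the travel-time functions.
make_friction <- function(mat, pixel_size = 12.5) {
  structure(list(grid = raster_grid(mat, pixel_size),
                 impassable = is.na(mat)),
            class = "friction_surface")
}

# Random small friction instance: some impassable cells, heterogeneous
# friction, origin guaranteed passable.
random_friction <- function(nr = 6, nc = 6, p_block = 0.15,
                            pixel_size = 12.5) {
  f <- matrix(exp(stats::runif(nr * nc, log(0.045), log(1.8))), nr, nc)
  f[stats::runif(nr * nc) < p_block] <- NA
  if (is.na(f[1, 1])) f[1, 1] <- 0.72
  make_friction(f, pixel_size)
}
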