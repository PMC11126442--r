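# Independent brute-force oracles for the rank tests. These deliberately
# re-derive everything from first principles (pair counting, explicit
# enumeration over sign vectors / group assignments) rather than reusing the
# package's generating-function or combn shortcuts.

# two-sided p as twice the smaller tail, capped at 1
oracle_two_sided <- function(stats, observed) {
  min(1, 2 * min(mean(stats <= observed + 1e-9), mean(stats >= observed - 1e-9)))
}

# signed-rank V for given signs over |d| mid-ranks
oracle_signed_rank_p <- function(x, y) {
  d <- (x - y)[x != y]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  vs <- apply(signs, 1, function(s) sum(r[s]))
  oracle_two_sided(vs, v_obs)
}

# Mann-Whitney U by direct pair counting (wins + half-ties), enumerated over
# every assignment of the pooled values to group A
oracle_u_stat <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

oracle_mann_whitney_p <- function(a, b) {
  pool <- c(a, b)
  na <- length(a)
  idx <- utils::combn(length(pool), na)
  us <- apply(idx, 2, function(i) oracle_u_stat(pool[i], pool[-i]))
  oracle_two_sided(us, oracle_u_stat(a, b))
}

# small quick-to-generate phantoms shared across tests
tiny_phantom_config <- function(..., seed = 101) {
  phantom_config(grid_shape = c(32, 32, 32), seed = seed, ...)
}

# a lesioned phantom whose single sphere sits under the second tooth's
# buccal_mid site
lesioned_phantom <- function(radius_mm = 3, contrast = 6, noise_sd = 10,
                             seed = 202, grid = c(40, 40, 40), ...) {
  cfg0 <- phantom_config(grid_shape = grid, seed = seed)
  g <- periomri:::phantom_geometry(cfg0)
  ctr <- (g$marrow_lo_mm + g$marrow_hi_mm) / 2
  phantom_config(
    grid_shape = grid, noise_sd = noise_sd,
    lesions_t0 = list(lesion(ctr, radius_mm, contrast)),
    seed = seed, ...
  )
}
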