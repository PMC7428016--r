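# Shared seeded fixture battery, generated once per test run.
.fixture_cache <- new.env(parent = emptyenv())

fixture_battery <- function(n = 100L) {
  key <- paste0("battery_", n)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- lapply(seq_len(n), random_drf_fixture)
  .fixture_cache[[key]]
}

# toy single-site molecule: one carbon with one hydrogen along `dir`
toy_ch <- function(dir) {
  dir <- dir / sqrt(sum(dir^2))
  molecule(c("C", "H"), rbind(c(0, 0, 0), 1.09 * dir), name = "toy-CH")
}

# a random 3D rotation matrix from a seed
random_rotation <- function(seed) {
  set.seed(seed)
  m <- matrix(rnorm(9), 3)
  qr.Q(qr(m)) * sign(det(qr.Q(qr(m))))
}
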