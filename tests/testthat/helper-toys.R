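# tiny constructors shared across test files

mk_im <- function(...) {
  image_matrix(rbind(...))
}

# hand-built orthonormal basis object (rows must be unit norm)
mk_basis <- function(components, center = NULL) {
  components <- rbind(components)
  structure(
    list(components = components,
         eigenvalues = rev(seq_len(nrow(components))),
         center = if (is.null(center)) rep(0, ncol(components)) else center,
         n_source = nrow(components) + 2L),
    class = "npv_basis"
  )
}

with_seed_ns <- function(seed, code) {
  f <- get("with_seed", asNamespace("codenoise"))
  f(seed, code)
}

rand_im <- function(n, j, seed, sd = 1) {
  with_seed_ns(seed, image_matrix(matrix(rnorm(n * j, sd = sd), n, j)))
}
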