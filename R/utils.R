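# internal geometry / misc helpers

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v, tol = 1e-12) {
  n <- vnorm(v)
  if (n < tol) abort("cannot normalize a (near) zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# deterministic child seeds below 2^31, derived from a master seed by a
# splitmix-style integer hash so any row of a study is reproducible alone
derive_seed <- function(master, index) {
  x <- (as.double(master) * 2654435761 + as.double(index) * 40503 + 97) %%
    2147483647
  as.integer(x) + 1L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
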