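# LP backends.
#
# The package bundles its own dense bounded-variable simplex (src/lp.cpp),
# which is exact and self-contained but quadratic per iteration — fine for
# the small LPs of unit tests and modest instances. The full planning LPs
# (thousands of dose rows) are delegated, when available, to HiGHS through
# the scipy `linprog` interface of the system `python`, with a one-shot
# sparse formulation. Both backends solve the identical formulation and
# are cross-checked in the test suite.

backend_env <- new.env(parent = emptyenv())

find_python <- function() {
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(p)
  }
  ""
}

#' LP backend in use
#'
#' `"highs"` (scipy/HiGHS via the system python) when available, else
#' `"simplex"` (the bundled solver). Override with
#' `options(sonoplan.lp_backend = "simplex"|"highs"|"auto")`.
#' @return Backend name, character.
#' @export
lp_backend <- function() {
  opt <- getOption("sonoplan.lp_backend", "auto")
  if (opt %in% c("simplex", "highs")) return(opt)
  if (is.null(backend_env$highs_ok)) {
    py <- find_python()
    backend_env$python <- py
    backend_env$highs_ok <- nzchar(py) &&
      suppressWarnings(system2(py, c("-c", shQuote("import scipy.optimize")),
                               stdout = FALSE, stderr = FALSE)) == 0
  }
  if (isTRUE(backend_env$highs_ok)) "highs" else "simplex"
}

# Solve min c'x s.t. sparse A x (sense) b, lo <= x <= hi with HiGHS.
# ai/aj/ax: 1-based triplets.
lp_solve_highs <- function(ai, aj, ax, m, n, b, sense, cc, lo, hi,
                           method = "highs") {
  indir <- tempfile("lpin")
  outdir <- tempfile("lpout")
  dir.create(indir)
  dir.create(outdir)
  on.exit(unlink(c(indir, outdir), recursive = TRUE), add = TRUE)
  wb <- function(name, v, int = FALSE) {
    con <- file(file.path(indir, paste0(name, ".bin")), "wb")
    if (int) writeBin(as.integer(v), con, size = 4L, endian = "little")
    else writeBin(as.numeric(v), con, size = 8L, endian = "little")
    close(con)
  }
  wb("ai", ai, int = TRUE)
  wb("aj", aj, int = TRUE)
  wb("ax", ax)
  wb("b", b)
  wb("sense", sense, int = TRUE)
  wb("c", cc)
  wb("lo", pmax(lo, -1e30))
  wb("hi", pmin(hi, 1e30))
  jsonlite::write_json(list(m = m, n = n, nnz = length(ax), method = method),
                       file.path(indir, "header.json"), auto_unbox = TRUE)
  script <- system.file("python", "lp_highs.py", package = "sonoplan")
  err <- tempfile()
  code <- system2(backend_env$python %||% find_python(),
                  c(shQuote(script), shQuote(indir), shQuote(outdir)),
                  stdout = err, stderr = err)
  resfile <- file.path(outdir, "result.json")
  if (code != 0 || !file.exists(resfile)) {
    abort(paste0("HiGHS backend failed: ",
                 paste(readLines(err, warn = FALSE), collapse = "\n")))
  }
  if (isTRUE(getOption("sonoplan.lp_debug"))) {
    message(paste(readLines(err, warn = FALSE), collapse = "\n"))
  }
  res <- jsonlite::read_json(resfile)
  x <- readBin(file.path(outdir, "x.bin"), "double", n = n, size = 8L,
               endian = "little")
  list(status = res$status, x = x, objective = res$objective)
}

# unified sparse solve: picks the backend; densifies for the bundled simplex
lp_solve_sparse <- function(ai, aj, ax, m, n, b, sense, cc, lo, hi,
                            basis0 = NULL, method = "highs-ipm") {
  # small instances skip the subprocess entirely; the bundled simplex is
  # faster there and exercises the same formulation
  if (lp_backend() == "highs" && m > 200) {
    # interior point with crossover: much faster than the dual simplex on
    # these dense-column dose LPs, and still returns a basic solution
    return(lp_solve_highs(ai, aj, ax, m, n, b, sense, cc, lo, hi, method))
  }
  A <- matrix(0, m, n)
  A[cbind(ai, aj)] <- ax
  lp_solve(A, b, sense, cc, lo, hi, basis0)
}
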