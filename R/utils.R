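# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_cfg <- function(field, msg) {
  stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}

stopifnot_counts <- function(x) {
  if (!methods::is(x, "sparseMatrix") && !is.matrix(x)) {
    stop("`counts` must be a matrix or sparse Matrix (genes x cells)", call. = FALSE)
  }
  if (length(x) == 0 || nrow(x) == 0 || ncol(x) == 0) {
    stop("`counts` is empty", call. = FALSE)
  }
  invisible(x)
}

as_dgc <- function(x) {
  if (methods::is(x, "dgCMatrix")) return(x)
  methods::as(methods::as(methods::as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

# Stage seeds are fanned out from one global seed by fixed offsets so any
# stage can be re-run in isolation and still reproduce the pipeline run.
stage_seed <- function(seed, stage) {
  offsets <- c(
    simulate = 0L, qc = 101L, cluster1 = 202L, subtypes = 303L,
    scoring = 404L, nmf = 505L, pseudobulk = 606L, deconv = 707L,
    stats = 808L, clinical = 909L
  )
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer((seed + offsets[[stage]]) %% .Machine$integer.max)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

row_vars_sparse <- function(x) {
  # E[x^2] - E[x]^2 with the n/(n-1) correction, without densifying.
  n <- ncol(x)
  mu <- Matrix::rowMeans(x)
  x2 <- x
  x2@x <- x2@x^2
  ex2 <- Matrix::rowMeans(x2)
  pmax((ex2 - mu^2) * n / (n - 1), 0)
}
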