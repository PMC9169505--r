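#' Posterior draws container
#'
#' Draws are stored per parameter as an (iteration x chain) matrix, plus
#' sampler metadata (seed, iterations, burn-in, thinning). Variance
#' parameters (names starting `sigma2` or `lambda2`) must be strictly
#' positive in every draw.
#'
#' @param draws named list of numeric (iteration x chain) matrices, one per
#'   parameter; all with identical dimensions.
#' @param seed,iterations,burn_in,thinning sampler metadata.
#' @return an object of class `"asb_draws"`.
#' @seealso [write_draws()], [as_mcmc_list()]
#' @export
asb_draws <- function(draws, seed = NA_integer_, iterations = NA_integer_,
                      burn_in = NA_integer_, thinning = 1L) {
  check_that(is.list(draws) && length(draws) > 0L,
             "`draws` must be a non-empty named list of matrices")
  check_that(!is.null(names(draws)) && all(nzchar(names(draws))),
             "all parameters must be named")
  draws <- lapply(draws, function(m) {
    if (is.numeric(m) && is.null(dim(m))) m <- matrix(m, ncol = 1L)
    m
  })
  dims <- vapply(draws, function(m) dim(m), integer(2))
  check_that(all(dims[1, ] == dims[1, 1]) && all(dims[2, ] == dims[2, 1]),
             "all parameters must share one (iteration, chain) shape")
  obj <- structure(
    list(draws = draws,
         meta = list(seed = seed, iterations = iterations,
                     burn_in = burn_in, thinning = thinning,
                     chains = ncol(draws[[1L]]),
                     kept = nrow(draws[[1L]]))),
    class = "asb_draws")
  validate_draws(obj)
  obj
}

validate_draws <- function(x) {
  stopifnot(inherits(x, "asb_draws"))
  vp <- grep("^(sigma2|lambda2)", names(x$draws), value = TRUE)
  for (p in vp) {
    check_that(all(x$draws[[p]] > 0),
               "variance parameter '%s' has non-positive draws", p)
  }
  invisible(x)
}

#' @export
print.asb_draws <- function(x, ...) {
  cat(sprintf("posterior draws: %d parameters, %d chains x %d kept iterations\n",
              length(x$draws), x$meta$chains, x$meta$kept))
  cat("parameters:", paste(utils::head(names(x$draws), 8L), collapse = ", "),
      if (length(x$draws) > 8L) "..." else "", "\n")
  invisible(x)
}

#' Flatten draws of one parameter across chains
#' @param x an `asb_draws` object.
#' @param parameter parameter name.
#' @return numeric vector of all draws (chains concatenated).
#' @export
draws_of <- function(x, parameter) {
  stopifnot(inherits(x, "asb_draws"))
  check_that(parameter %in% names(x$draws), "no parameter '%s' in draws", parameter)
  as.vector(x$draws[[parameter]])
}

#' Convert to a coda mcmc.list
#' @param x an `asb_draws` object.
#' @return a [coda::mcmc.list] with one column per parameter.
#' @export
as_mcmc_list <- function(x) {
  stopifnot(inherits(x, "asb_draws"))
  nch <- x$meta$chains
  coda::mcmc.list(lapply(seq_len(nch), function(ch) {
    m <- vapply(x$draws, function(d) d[, ch], numeric(x$meta$kept))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1L, dimnames = list(NULL, names(x$draws)))
    coda::mcmc(m)
  }))
}

#' Write and read posterior draws
#'
#' Draw files are plain text: a long CSV (`parameter,chain,iteration,value`)
#' with values printed at full double precision, plus a JSON metadata sidecar
#' at `<path>.json`. `read_draws(write_draws(x, path))` reproduces `x`
#' bit-exactly.
#'
#' @param x an `asb_draws` object.
#' @param path CSV file path (the sidecar is written next to it).
#' @return `write_draws()`: `path`, invisibly; `read_draws()`: the
#'   reconstructed `asb_draws` object.
#' @export
write_draws <- function(x, path) {
  validate_draws(x)
  nm <- names(x$draws)
  nit <- x$meta$kept
  nch <- x$meta$chains
  rows <- do.call(rbind, lapply(nm, function(p) {
    m <- x$draws[[p]]
    data.frame(parameter = p,
               chain = rep(seq_len(nch), each = nit),
               iteration = rep(seq_len(nit), times = nch),
               value = sprintf("%.17g", as.vector(m)),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(x$meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_draws
#' @export
read_draws <- function(path) {
  check_that(file.exists(path), "draws file not found: %s", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("parameter", "chain", "iteration", "value")
  check_that(all(need %in% names(tab)),
             "malformed draws file %s: expected columns %s", path,
             paste(need, collapse = ","))
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  draws <- lapply(split(tab, tab$parameter), function(d) {
    nit <- max(d$iteration)
    nch <- max(d$chain)
    check_that(nrow(d) == nit * nch,
               "malformed draws file: parameter '%s' has %d rows for %d x %d grid",
               d$parameter[1L], nrow(d), nit, nch)
    m <- matrix(NA_real_, nit, nch)
    m[cbind(d$iteration, d$chain)] <- as.numeric(d$value)
    check_that(!anyNA(m), "malformed draws file: parameter '%s' has missing cells",
               d$parameter[1L])
    m
  })
  # preserve original parameter order
  draws <- draws[unique(tab$parameter)]
  asb_draws(draws,
            seed = meta$seed %||% NA_integer_,
            iterations = meta$iterations %||% NA_integer_,
            burn_in = meta$burn_in %||% NA_integer_,
            thinning = meta$thinning %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
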