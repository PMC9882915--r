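#' MCMC sampler settings
#'
#' Settings shared by all JAGS-based fits in the package. Defaults are sized
#' for the package's default synthetic scale (a dozen surveys, a few hundred
#' strata): 4 chains of 1000 adaptation/burn-in and 1000 retained iterations.
#'
#' @param chains number of independent chains.
#' @param warmup adaptation + burn-in iterations per chain (discarded).
#' @param iter retained sampling iterations per chain.
#' @param thin thinning interval applied to the retained iterations.
#' @param seed integer; base RNG seed. Chain `j` uses `seed + j - 1` with
#'   JAGS's Mersenne-Twister RNG, so runs are reproducible bit-for-bit.
#' @param quiet suppress JAGS progress output.
#' @return an object of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 4, warmup = 1000, iter = 1000, thin = 1,
                        seed = 1, quiet = TRUE) {
  stopifnot(chains >= 1, warmup >= 100, iter >= 10, thin >= 1,
            is.finite(seed))
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 iter = as.integer(iter), thin = as.integer(thin),
                 seed = as.integer(seed), quiet = isTRUE(quiet)),
            class = "mcmc_config")
}

#' Split-chain potential scale reduction factor
#'
#' Computes split-\eqn{\hat{R}} (each chain halved, rank-preserving but on the
#' raw scale) for every monitored scalar. Values near 1 indicate between-chain
#' agreement; the package's fitters warn above 1.05.
#'
#' @param sims array of draws, `iterations x chains x parameters`, or a matrix
#'   `iterations x chains` for a single parameter.
#' @return named numeric vector of \eqn{\hat{R}} values.
#' @export
split_rhat <- function(sims) {
  if (length(dim(sims)) == 2L) dim(sims) <- c(dim(sims), 1L)
  n <- dim(sims)[1L]
  half <- n %/% 2L
  apply(sims, 3L, function(x) {
    # split each chain into first/second half -> 2*chains sequences
    splits <- cbind(x[seq_len(half), , drop = FALSE],
                    x[(n - half + 1L):n, , drop = FALSE])
    m <- ncol(splits); len <- nrow(splits)
    mu <- colMeans(splits)
    s2 <- apply(splits, 2L, stats::var)
    W <- mean(s2)
    B <- len * stats::var(mu)
    if (W == 0) return(1)
    sqrt((W * (len - 1) / len + B / len) / W)
  })
}

# Run a JAGS model and return per-chain draws.
#
# Returns list(draws = matrix [chains*iter, P] of merged draws,
#              sims  = array [iter, chains, P],
#              rhat  = named vector). `inits_extra` allows fixed inits.
run_jags <- function(model_string, data, monitor, mcmc,
                     inits_extra = NULL) {
  stopifnot(inherits(mcmc, "mcmc_config"))
  inits <- lapply(seq_len(mcmc$chains), function(j) {
    ini <- list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = mcmc$seed + j - 1L)
    c(ini, inits_extra)
  })
  con <- textConnection(model_string)
  on.exit(close(con), add = TRUE)
  rjags::load.module("glm", quiet = TRUE)
  if (mcmc$quiet) {
    pb <- "none"
    jm <- suppressWarnings(suppressMessages(
      rjags::jags.model(con, data = data, inits = inits,
                        n.chains = mcmc$chains, n.adapt = mcmc$warmup,
                        quiet = TRUE)))
  } else {
    pb <- "text"
    jm <- rjags::jags.model(con, data = data, inits = inits,
                            n.chains = mcmc$chains, n.adapt = mcmc$warmup)
  }
  update(jm, n.iter = mcmc$warmup, progress.bar = pb)
  samp <- rjags::coda.samples(jm, variable.names = monitor,
                              n.iter = mcmc$iter * mcmc$thin,
                              thin = mcmc$thin, progress.bar = pb)
  pn <- colnames(samp[[1L]])
  sims <- array(NA_real_,
                dim = c(nrow(samp[[1L]]), length(samp), length(pn)),
                dimnames = list(NULL, NULL, pn))
  for (j in seq_along(samp)) sims[, j, ] <- as.matrix(samp[[j]])
  draws <- do.call(rbind, lapply(samp, as.matrix))
  list(draws = draws, sims = sims, rhat = split_rhat(sims))
}

# Column extractor tolerant of JAGS's `name[i]` indexing.
jags_cols <- function(draws, name, n) {
  if (n == 1L && name %in% colnames(draws))
    return(draws[, name, drop = FALSE])
  cols <- paste0(name, "[", seq_len(n), "]")
  miss <- setdiff(cols, colnames(draws))
  if (length(miss)) stop("missing monitored columns: ",
                         paste(miss, collapse = ", "))
  draws[, cols, drop = FALSE]
}

warn_if_unconverged <- function(rhat, label, tol = 1.05) {
  bad <- rhat[is.finite(rhat) & rhat > tol]
  if (length(bad)) {
    warning(sprintf("%s: %d parameter(s) with split-Rhat > %.2f (max %.3f: %s)",
                    label, length(bad), tol, max(bad),
                    names(which.max(bad))), call. = FALSE)
    return(TRUE)
  }
  FALSE
}
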