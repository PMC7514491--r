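#' Run a mixing-parameter benchmark sweep
#'
#' For each mixing value and replicate: generate an LFR-style instance, run
#' the seeded detector (and optionally the random-initialization k-means
#' baseline), and score the result against the planted partition with NMI
#' and bidirectional F1. Replicate seeds are derived deterministically from
#' `seed`, so the whole sweep is reproducible from the returned manifest.
#'
#' @param params_fn Function `mu -> lfr_params` describing the family.
#' @param mu_values Mixing values to sweep.
#' @param replicates Instances per mixing value (default 5).
#' @param algorithms Subset of `c("ddjkm", "random_kmeans")`.
#' @param h,max_iter Passed to the detectors.
#' @param seed Master integer seed.
#' @param out_prefix Optional path prefix; when given, writes
#'   `<prefix>.tsv` (per-run rows) and `<prefix>.manifest.json`.
#' @return A data.frame with one row per (mu, replicate, algorithm):
#'   columns `mu`, `replicate`, `algorithm`, `nmi`, `f1`, `K`,
#'   `iterations`, `realized_mu`, `seed_used`. Generation failures are
#'   skipped with a warning naming the reason.
#' @export
run_benchmark <- function(params_fn, mu_values, replicates = 5,
                          algorithms = c("ddjkm", "random_kmeans"),
                          h = 3, max_iter = 100, seed = 1,
                          out_prefix = NULL) {
  stopifnot(replicates >= 1)
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  n_seeds <- length(mu_values) * replicates
  sub_seeds <- withr::with_seed(as.integer(seed),
                                sample.int(.Machine$integer.max, 2L * n_seeds))
  rows <- list()
  idx <- 0L
  for (mu in mu_values) {
    for (r in seq_len(replicates)) {
      idx <- idx + 1L
      gen_seed <- sub_seeds[idx]
      inst <- tryCatch(generate_lfr(params_fn(mu), seed = gen_seed),
                       error = function(e) e)
      if (inherits(inst, "error")) {
        warning(sprintf("generation failed at mu=%.2f rep %d: %s",
                        mu, r, conditionMessage(inst)))
        next
      }
      for (alg in algorithms) {
        res <- switch(alg,
          ddjkm = ddjkm_detect(inst$graph, K = inst$K, h = h,
                               max_iter = max_iter),
          random_kmeans = random_init_kmeans(inst$graph, K = inst$K,
                                             rng_seed = sub_seeds[n_seeds + idx],
                                             max_iter = max_iter))
        rows[[length(rows) + 1L]] <- data.frame(
          mu = mu, replicate = r, algorithm = alg,
          nmi = nmi(inst$membership, res$membership),
          f1 = f1_score(inst$membership, res$membership),
          K = inst$K, iterations = res$iterations,
          realized_mu = inst$realized_mu, seed_used = gen_seed)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_prefix)) {
    write.table(out, paste0(out_prefix, ".tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest <- list(mu_values = mu_values, replicates = replicates,
                     algorithms = algorithms, h = h, max_iter = max_iter,
                     seed = seed,
                     params = lapply(mu_values,
                                     function(m) unclass(params_fn(m))),
                     version = as.character(utils::packageVersion("ddjkm")))
    jsonlite::write_json(manifest, paste0(out_prefix, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Summarize a benchmark sweep
#'
#' @param results Data frame from [run_benchmark()].
#' @return One row per (mu, algorithm) with mean and standard deviation of
#'   NMI and F1 and the replicate count.
#' @export
summarize_benchmark <- function(results) {
  agg <- function(f) stats::aggregate(cbind(nmi, f1) ~ mu + algorithm,
                                      data = results, FUN = f)
  m <- agg(mean); s <- agg(sd); n <- agg(length)
  out <- data.frame(mu = m$mu, algorithm = m$algorithm,
                    mean_nmi = m$nmi, sd_nmi = s$nmi,
                    mean_f1 = m$f1, sd_f1 = s$f1,
                    replicates = n$nmi)
  out[order(out$algorithm, out$mu), ]
}

#' Predefined benchmark parameter families
#'
#' Convenience constructors for the benchmark families used in the package's
#' own experiments: `"lfr1"` (1000 nodes, community sizes 20-50, mean degree
#' 20, max degree 50) and `"lfr4"` (5000 nodes, community sizes 20-100, mean
#' degree 15, max degree 75).
#'
#' @param name `"lfr1"` or `"lfr4"`.
#' @return A function `mu -> lfr_params` usable as `params_fn` in
#'   [run_benchmark()].
#' @export
lfr_family <- function(name) {
  switch(name,
    lfr1 = function(mu) lfr_params(n = 1000, tau1 = 2, tau2 = 1,
                                   c_min = 20, c_max = 50,
                                   k_avg = 20, k_max = 50, mu = mu),
    lfr4 = function(mu) lfr_params(n = 5000, tau1 = 2, tau2 = 1,
                                   c_min = 20, c_max = 100,
                                   k_avg = 15, k_max = 75, mu = mu),
    stop("unknown family: ", name))
}
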