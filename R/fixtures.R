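#' Benchmark simulation scenarios
#'
#' Deterministic one-factor-at-a-time scenario grid around the reference
#' setting (ten clones, no unobserved clones, 20 cells, 200 sites, false
#' positive rate 0.2, false negative rate 0.1, 20\% missing values), five
#' replicates per scenario with fixed seeds. Varied axes: number of
#' cells, number of clones (including the degenerate single-clone case
#' and the five-clone case, whose replicates can be linear trees), number
#' of sites, missing-value fraction, noise level and number of unobserved
#' clones. The exact levels are this package's choices.
#'
#' @param n_replicates replicates per scenario (default 5)
#' @return named list of scenarios; each is a list with `name`, `config`
#'   (a [simulation_config()]), `n_replicates` and `seeds`
#' @export
build_scenarios <- function(n_replicates = 5) {
  base <- list(n_clones = 10, n_unobserved = 0, n_cells = 20,
               n_sites = 200, alpha = 0.2, beta = 0.1, p_missing = 0.2)
  variant <- function(...) utils::modifyList(base, list(...))
  specs <- list(
    default       = base,
    cells_10      = variant(n_cells = 10),
    cells_50      = variant(n_cells = 50),
    clones_1      = variant(n_clones = 1),
    clones_5      = variant(n_clones = 5),
    clones_15     = variant(n_clones = 15),
    sites_50      = variant(n_sites = 50),
    sites_500     = variant(n_sites = 500),
    missing_0     = variant(p_missing = 0),
    missing_40    = variant(p_missing = 0.4),
    low_noise     = variant(alpha = 1e-5, beta = 0.1),
    high_noise    = variant(alpha = 0.3, beta = 0.2),
    unobserved_2  = variant(n_unobserved = 2)
  )
  out <- vector("list", length(specs))
  names(out) <- names(specs)
  for (i in seq_along(specs)) {
    out[[i]] <- list(
      name = names(specs)[i],
      config = do.call(simulation_config, specs[[i]]),
      n_replicates = as.integer(n_replicates),
      seeds = as.integer(i * 1000L + seq_len(n_replicates)))
  }
  out
}

#' Simulate one replicate of a scenario
#'
#' @param scenario an element of [build_scenarios()]
#' @param replicate replicate index in `1..n_replicates`
#' @return as [simulate_dataset()]; regenerating a replicate from its
#'   recorded seed is bit-identical
#' @export
simulate_scenario <- function(scenario, replicate = 1) {
  if (replicate < 1 || replicate > scenario$n_replicates)
    stop("replicate out of range")
  cfg <- scenario$config
  cfg$seed <- scenario$seeds[replicate]
  simulate_dataset(cfg)
}

#' Write scenario fixtures to disk
#'
#' Directory layout `<dir>/<scenario>/<replicate>/` with files
#' `genotypes.tsv`, `truth_tree.tsv`, `theta.tsv` and `meta.json` (the
#' configuration and seed).
#'
#' @param scenario an element of [build_scenarios()]
#' @param dir output directory
#' @return invisibly, the scenario directory
#' @export
write_scenario <- function(scenario, dir) {
  sdir <- file.path(dir, scenario$name)
  for (r in seq_len(scenario$n_replicates)) {
    rdir <- file.path(sdir, r)
    dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
    sim <- simulate_scenario(scenario, r)
    write_genotypes(sim$genotypes, file.path(rdir, "genotypes.tsv"))
    write_tree(sim$truth$tree, file.path(rdir, "truth_tree.tsv"))
    utils::write.table(
      data.frame(site = colnames(sim$genotypes),
                 clone = sim$truth$theta),
      file.path(rdir, "theta.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    meta <- unclass(scenario$config)
    meta$seed <- scenario$seeds[r]
    jsonlite::write_json(meta, file.path(rdir, "meta.json"),
                         auto_unbox = TRUE, null = "null")
  }
  invisible(sdir)
}
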