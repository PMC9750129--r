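#' Validate a pipeline configuration file
#'
#' Reads a YAML run configuration, type- and range-checks it, and fills in
#' defaults. The configuration mirrors the package's parameter objects:
#' `simulate.model` fields go to [demographic_model()], `simulate.damage`
#' to [damage_params()], `call` to [consensify_params()], `windows` to
#' [window_config()], `direction` to [direction_config()].
#'
#' @param path YAML file, or a list already in memory.
#' @return Object of class `"run_config"`.
#' @examples
#' cfg <- validate_config(list(seed = 1, output_dir = tempfile(),
#'                             stages = "simulate",
#'                             simulate = list(n_windows = 2,
#'                                             window_length = 100)))
#' cfg$seed
#' @export
validate_config <- function(path) {
  raw <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    yaml::read_yaml(path)
  } else if (is.list(path)) {
    path
  } else {
    stop("`path` must be a file path or a list", call. = FALSE)
  }
  known <- c("seed", "output_dir", "stages", "log_level", "simulate", "call",
             "dstat", "windows", "direction", "diversity", "mito")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  stages_all <- c("simulate", "call", "dstat", "windows", "direction",
                  "diversity", "mito")
  stages <- raw$stages %||% stages_all
  bad <- setdiff(stages, stages_all)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  stochastic <- c("simulate", "call", "direction")
  if (any(stages %in% stochastic) && is.null(raw$seed)) {
    stop("`seed` is mandatory when running stochastic stages (",
         paste(intersect(stages, stochastic), collapse = ", "), ")",
         call. = FALSE)
  }
  seed <- as.integer(raw$seed %||% 1L)

  sim <- raw$simulate %||% list()
  model_args <- sim$model %||% list()
  if (!is.null(model_args$pulse)) {
    model_args$pulse <- as.list(model_args$pulse)
  }
  if (!is.null(model_args$samples)) {
    model_args$samples <- unlist(model_args$samples)
  }
  if (!is.null(model_args$pop_size)) {
    model_args$pop_size <- unlist(model_args$pop_size)
  }
  model <- do.call(demographic_model, model_args)  # range checks live there
  damage <- if (!is.null(sim$damage)) do.call(damage_params, as.list(sim$damage))

  cfg <- list(
    seed = seed,
    output_dir = raw$output_dir %||% "paleoquartet_run",
    stages = stages,
    log_level = raw$log_level %||% "info",
    simulate = list(model = model,
                    n_windows = as.integer(sim$n_windows %||% 100L),
                    window_length = as.integer(sim$window_length %||% 5000L),
                    damage = damage),
    call = utils::modifyList(list(mode = "consensify", max_depth = "auto"),
                             as.list(raw$call %||% list())),
    dstat = utils::modifyList(list(p1 = "sable1", p2 = "blue1", p3 = "roan1",
                                   outgroup = "outgroup", block_size = 1e6),
                              as.list(raw$dstat %||% list())),
    windows = do.call(window_config, as.list(raw$windows %||% list())),
    direction = do.call(direction_config, as.list(raw$direction %||% list())),
    mito = as.list(raw$mito %||% list())
  )
  if (cfg$simulate$n_windows < 1 || cfg$simulate$window_length < 1) {
    stop("simulate.n_windows and simulate.window_length must be >= 1",
         call. = FALSE)
  }
  if (!cfg$call$mode %in% c("consensify", "random")) {
    stop("call.mode must be consensify or random", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic per-stage seed fan-out from the global seed
stage_seed <- function(seed, stage) {
  idx <- match(stage, c("simulate", "call", "dstat", "windows", "direction",
                        "diversity", "mito"))
  as.integer((as.numeric(seed) + 1000003 * idx) %% 2147483647)
}

#' Run the seeded end-to-end pipeline
#'
#' Executes the selected stages in dependency order
#' (simulate, call, windows, dstat, direction, diversity, mito), writing
#' all outputs (FASTA, TSV, newick, log) under `config$output_dir`, and
#' returns a manifest listing every output file with its checksum. Stage
#' seeds are derived deterministically from the global seed, so reruns with
#' the same configuration are byte-identical and stages can be rerun
#' independently.
#'
#' @param config A `"run_config"` from [validate_config()] (or a path/list
#'   accepted by it).
#' @return Tibble manifest: `stage`, `file`, `md5`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$output_dir, ...)
  manifest <- list()
  note <- function(stage, files) {
    manifest[[length(manifest) + 1L]] <<-
      tibble::tibble(stage = stage, file = basename(files),
                     md5 = unname(tools::md5sum(files)))
  }
  log_lines <- c(sprintf("paleoquartet run, global seed %d", config$seed),
                 sprintf("stages: %s", paste(config$stages, collapse = ", ")))

  order_all <- c("simulate", "call", "windows", "dstat", "direction",
                 "diversity", "mito")
  stages <- intersect(order_all, config$stages)

  for (stage in stages) {
    sd <- stage_seed(config$seed, stage)
    log_lines <- c(log_lines, sprintf("stage %s: seed %d", stage, sd))
    files <- switch(
      stage,
      simulate = stage_simulate(config, out, sd),
      call = stage_call(config, out, sd),
      windows = stage_windows(config, out),
      dstat = stage_dstat(config, out),
      direction = stage_direction(config, out, sd),
      diversity = stage_diversity(config, out),
      mito = stage_mito(config, out)
    )
    note(stage, files)
  }
  log_file <- out("run_log.txt")
  writeLines(log_lines, log_file)
  note("log", log_file)
  dplyr::bind_rows(manifest)
}

stage_simulate <- function(config, out, sd) {
  sim <- config$simulate
  truth <- simulate_cohort(sim$model, sim$n_windows, sim$window_length,
                           rng_seed = sd, keep_genotypes = TRUE,
                           keep_trees = TRUE)
  inds <- unique(sub("_[12]$", "", rownames(truth$windows[[1]]$genotypes)))
  files <- character(0)
  # truth haplotypes as FASTA, one record per haplotype
  for (ind in inds) {
    haps <- lapply(truth$windows, function(w) {
      g <- genotypes_by_individual(w$genotypes)[[ind]]
      apply(g, 1, decode_bases, collapse = TRUE)
    })
    haps <- do.call(rbind, lapply(haps, function(h) h))
    seqs <- apply(haps, 2, paste, collapse = "")
    names(seqs) <- if (length(seqs) == 1) ind
                   else paste0(ind, "_", seq_along(seqs))
    f <- out(paste0("truth_", ind, ".fasta"))
    write_fasta(seqs, f)
    files <- c(files, f)
  }
  # base counts through the observation model
  set.seed(sd + 1L)
  dp <- sim$damage %||% clean_params()
  counts_tabs <- list()
  for (ind in inds) {
    per_window <- lapply(truth$windows, function(w) {
      apply_damage_and_coverage(genotypes_by_individual(w$genotypes)[[ind]],
                                dp)
    })
    counts <- do.call(rbind, lapply(per_window, unclass))
    counts_tabs[[ind]] <- base_counts_table(counts, ind)
  }
  f_counts <- out("base_counts.tsv")
  write_base_counts(dplyr::bind_rows(counts_tabs), f_counts)
  # gene trees
  f_trees <- out("gene_trees.nwk")
  writeLines(vapply(truth$windows,
                    function(w) ape::write.tree(w$tree$phylo), character(1)),
             f_trees)
  c(files, f_counts, f_trees)
}

stage_call <- function(config, out, sd) {
  f_counts <- out("base_counts.tsv")
  if (!file.exists(f_counts)) {
    stop("call stage requires base counts from the simulate stage (",
         f_counts, " not found)", call. = FALSE)
  }
  tab <- utils::read.table(f_counts, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  files <- character(0)
  for (ind in unique(tab$individual)) {
    counts <- read_base_counts(f_counts, individual = ind)
    params <- consensify_params(max_depth = config$call$max_depth)
    g <- call_genome(counts, mode = config$call$mode, params = params,
                     rng_seed = sd + match(ind, unique(tab$individual)),
                     individual = ind)
    f <- out(paste0("called_", ind, ".fasta"))
    write_fasta(stats::setNames(g$sequences, names(g$sequences)), f)
    files <- c(files, f)
  }
  files
}

called_genomes <- function(config, out) {
  files <- list.files(config$output_dir, pattern = "^called_.*\\.fasta$",
                      full.names = TRUE)
  if (!length(files)) {
    stop("stage requires called genomes (run the call stage first)",
         call. = FALSE)
  }
  genomes <- lapply(files, read_fasta)
  names(genomes) <- sub("^called_(.*)\\.fasta$", "\\1", basename(files))
  genomes
}

# one representative per species role, for quartet stages
quartet_subset <- function(genomes) {
  roles <- c("blue", "sable", "roan", "outgroup")
  picks <- vapply(roles, function(r) {
    hit <- sort(names(genomes)[startsWith(names(genomes), r)])
    if (!length(hit)) stop("no called genome for role ", r, call. = FALSE)
    hit[1]
  }, character(1))
  genomes[picks]
}

stage_windows <- function(config, out) {
  recs <- window_trees(quartet_subset(called_genomes(config, out)),
                       config$windows)
  f_recs <- out("window_trees.tsv")
  utils::write.table(recs[, setdiff(names(recs), "sites")], f_recs,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  f_trees <- out("window_trees.trees")
  write_window_trees(recs, f_trees)
  f_sum <- out("topology_summary.tsv")
  utils::write.table(topology_summary(recs), f_sum, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  c(f_recs, f_trees, f_sum)
}

stage_dstat <- function(config, out) {
  genomes <- called_genomes(config, out)
  cfg <- config$dstat
  need <- unlist(cfg[c("p1", "p2", "p3", "outgroup")])
  missing <- setdiff(need, names(genomes))
  if (length(missing)) {
    stop("dstat taxa not among called genomes: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  res <- dstat(genomes[[cfg$p1]], genomes[[cfg$p2]], genomes[[cfg$p3]],
               genomes[[cfg$outgroup]], block_size = cfg$block_size)
  f <- out("dstat.tsv")
  utils::write.table(tidy(res), f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  f
}

stage_direction <- function(config, out, sd) {
  f_recs <- out("window_trees.tsv")
  if (!file.exists(f_recs)) {
    stop("direction stage requires window records (run the windows stage)",
         call. = FALSE)
  }
  recs <- utils::read.table(f_recs, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  res <- direction_test(
    recs$rs_path_proportion[recs$topology_class == "BS"],
    recs$rs_path_proportion[recs$topology_class == "BR"],
    config$direction, rng_seed = sd
  )
  f <- out("direction.tsv")
  utils::write.table(tidy(res), f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  f
}

stage_diversity <- function(config, out) {
  genomes <- called_genomes(config, out)
  res <- diversity_table(genomes)
  f1 <- out("diversity_pairs.tsv")
  utils::write.table(res$pairs, f1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  f2 <- out("diversity_species.tsv")
  utils::write.table(res$species_means, f2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(f1, f2)
}

stage_mito <- function(config, out) {
  if (is.null(config$mito$alignment)) {
    stop("mito stage requires mito.alignment (aligned FASTA path)",
         call. = FALSE)
  }
  res <- mito_diversity(config$mito$alignment)
  f <- out("mito_diversity.tsv")
  utils::write.table(tidy(res), f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  f
}
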