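#' Configuration for an end-to-end synthetic run
#'
#' Collects every tunable of the pipeline in one object that is
#' serialized next to the outputs for provenance. All randomness flows
#' from `seed`; stage-specific seeds are derived from it
#' deterministically.
#'
#' @param out_dir output directory.
#' @param seed master integer seed.
#' @param families list of [sat_family_spec()].
#' @param target_family family_id whose monomer haplotypes are analyzed.
#' @param groups named character vector: library label -> group label
#'   (e.g. karyomorph x sex) for the exclusivity statistics.
#' @param genotypes a [genotype_sim_spec()], or `NULL` to skip the SLM
#'   stage.
#' @param read_length,n_reads_per_library,background_bp simulator sizes.
#' @param min_identity identity floor (percent) for read mapping and
#'   monomer excision.
#' @param min_aligned minimum aligned bp for read mapping.
#' @param candidate_threshold sex-ratio fold for candidate flagging.
#' @param family_threshold percent identity defining a shared family in
#'   catalog comparison.
#' @param max_missing missing calls tolerated per locus in the SLM scan.
#' @param het_prob `"auto"` or a number for the chance expectation.
#' @param stages character vector of stages to run, in order, from
#'   `c("simulate", "abundance", "haplotypes", "slm")`.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1, families = list(),
                       target_family = NULL, groups = NULL,
                       genotypes = NULL, read_length = 150,
                       n_reads_per_library = 1000, background_bp = 30000,
                       min_identity = 80, min_aligned = 28,
                       candidate_threshold = 1.5, family_threshold = 50,
                       max_missing = 0, het_prob = "auto",
                       stages = c("simulate", "abundance", "haplotypes",
                                  "slm")) {
  stopifnot(min_identity >= 0, min_identity <= 100,
            candidate_threshold >= 1,
            family_threshold >= 0, family_threshold <= 100)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 families = families, target_family = target_family,
                 groups = groups, genotypes = genotypes,
                 read_length = read_length,
                 n_reads_per_library = n_reads_per_library,
                 background_bp = background_bp,
                 min_identity = min_identity, min_aligned = min_aligned,
                 candidate_threshold = candidate_threshold,
                 family_threshold = family_threshold,
                 max_missing = max_missing, het_prob = het_prob,
                 stages = stages),
            class = "run_config")
}

#' Run the synthetic satellitome + sex-linked-marker pipeline
#'
#' Executes the requested stages in order — simulate reads/genotypes,
#' read mapping with male:female abundance ratios, monomer haplotype
#' extraction with singleton filtering, MST, and group exclusivity, and
#' the sex-linked marker screen — writing every result as plain-text
#' files under `config$out_dir` plus a JSON manifest with the MD5 hash
#' of every output. With a fixed seed the manifest is identical across
#' runs.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly, as a list (`outputs` maps file name
#'   to MD5 hash; stage results under `results`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  results <- list()
  files <- character(0)
  stages <- config$stages
  sim <- NULL

  needs_reads <- any(c("abundance", "haplotypes") %in% stages)
  if ("simulate" %in% stages || needs_reads) {
    if (length(config$families) > 0) {
      sim <- simulate_sat_reads(config$families,
                                read_length = config$read_length,
                                n_reads_per_library =
                                  config$n_reads_per_library,
                                seed = config$seed,
                                background_bp = config$background_bp)
      for (lib in names(sim$reads))
        files <- c(files, write_fastq(sim$reads[[lib]],
                                      out(paste0(lib, ".fastq"))))
      cat_seqs <- Biostrings::DNAStringSet(unlist(sim$truth$families))
      files <- c(files, write_fasta(cat_seqs, out("catalog.fasta")))
      files <- c(files, write_tsv(sim$truth$haplotypes,
                                  out("truth_haplotypes.tsv")))
    }
    if (!is.null(config$genotypes)) {
      gt <- simulate_genotypes(config$genotypes)
      results$genotypes_truth <- gt$truth
      files <- c(files,
                 write_genotype_csv(gt$matrix, out("genotypes.csv")),
                 write_sexmap_csv(gt$sexmap, out("sexmap.csv")))
    }
  }

  catalog <- if (!is.null(sim))
    stats::setNames(unlist(sim$truth$families), names(sim$truth$families))

  if ("abundance" %in% stages) {
    if (is.null(sim)) stop("pipeline stage 'abundance' failed: no reads ",
                           "(simulate stage required)")
    maps <- lapply(names(sim$reads), function(lib) {
      res <- map_reads(sim$reads[[lib]], catalog,
                       min_identity = config$min_identity,
                       min_aligned = config$min_aligned)
      files <<- c(files, write_tsv(res, out(paste0("abundance_", lib,
                                                   ".tsv"))))
      res
    })
    names(maps) <- names(sim$reads)
    results$abundance <- maps
    male_lib <- grep("male", names(maps), value = TRUE)
    male_lib <- setdiff(male_lib, grep("female", male_lib, value = TRUE))
    female_lib <- grep("female", names(maps), value = TRUE)
    if (length(male_lib) == 1 && length(female_lib) == 1) {
      sr <- sex_ratio(maps[[male_lib]], maps[[female_lib]],
                      candidate_threshold = config$candidate_threshold)
      files <- c(files, write_tsv(sr, out("sex_ratio.tsv")))
      results$sex_ratio <- sr
    }
  }

  if ("haplotypes" %in% stages) {
    if (is.null(sim)) stop("pipeline stage 'haplotypes' failed: no reads")
    target <- config$target_family
    if (is.null(target)) target <- names(sim$truth$families)[1]
    cons <- sim$truth$families[[target]]
    monomers <- do.call(rbind, lapply(names(sim$reads), function(lib)
      extract_monomers(sim$reads[[lib]], cons, library = lib,
                       min_identity = config$min_identity)))
    nodes <- filter_singletons(monomers)
    files <- c(files, write_tsv(nodes, out("haplotype_nodes.tsv")))
    if (nrow(nodes) > 0) {
      mst <- build_mst(nodes)
      files <- c(files, write_tsv(mst$edges, out("haplotype_mst_edges.tsv")),
                 write_graphml(mst, out("haplotype_mst.graphml")))
      results$mst <- mst
      if (!is.null(config$groups))
        results$group_stats <- group_stats(mst, config$groups)
    }
    results$haplotype_nodes <- nodes
  }

  if ("slm" %in% stages) {
    gt_path <- out("genotypes.csv")
    if (!file.exists(gt_path)) stop("pipeline stage 'slm' failed: no ",
                                    "genotype matrix")
    gm <- read_genotype_csv(gt_path)
    sm <- read_sexmap_csv(out("sexmap.csv"))
    screen <- slm_screen(gm, sm, max_missing = config$max_missing,
                         het_prob = config$het_prob)
    results$slm <- screen
    rep <- data.frame(
      pattern = c("XY", "ZW"),
      observed = c(length(screen$xy_loci), length(screen$zw_loci)),
      expected_by_chance = c(screen$expected_by_chance_xy,
                             screen$expected_by_chance_zw),
      p_poisson = c(screen$p_xy, screen$p_zw))
    files <- c(files, write_tsv(rep, out("slm_report.tsv")))
    jsonlite::write_json(list(verdict = screen$verdict,
                              xy_loci = screen$xy_loci,
                              zw_loci = screen$zw_loci),
                         out("slm_verdict.json"), auto_unbox = TRUE)
    files <- c(files, out("slm_verdict.json"))
  }

  # out_dir is excluded so that identical runs in different directories
  # produce identical manifests
  cfg_txt <- vapply(setdiff(names(config), "out_dir"), function(k)
    paste0(k, " = ", paste(utils::capture.output(dput(config[[k]])),
                           collapse = " ")), character(1))
  writeLines(cfg_txt, out("run_config.txt"))
  files <- c(files, out("run_config.txt"))

  hashes <- tools::md5sum(unique(files))
  manifest <- list(seed = config$seed, stages = stages,
                   outputs = as.list(stats::setNames(unname(hashes),
                                                     basename(names(hashes)))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  manifest$results <- results
  invisible(manifest)
}
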