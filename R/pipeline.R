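# End-to-end orchestration: simulate -> preprocess -> map -> signatures ->
# abundance -> report. Intermediate artifacts are flat TSVs in one directory
# per run; the final report is JSON. Identical config + seed gives identical
# outputs.

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order on either a simulated dataset
#' (default) or user-supplied inputs, writing intermediate TSVs, a MANIFEST
#' of completed stages, and a machine-readable JSON report. All randomness
#' derives from the seed carried by `config`.
#'
#' Stages: `simulate` (build genome + truth + FASTQ), `preprocess` (adapter/
#' UMI parsing, deduplication, rRNA/spike classification), `map` (ungapped
#' alignment, feature assignment, length profiles, nucleotide composition),
#' `signatures` (long RNA 5'-end merging, pre-pre-piRNA calls, overlap
#' spectra with Z10, phasing metaplot and period), `abundance` (spike-in
#' calibrated absolute quantification).
#'
#' @param config A [sim_config()] (or path to a YAML file of its fields,
#'   optionally with a `stages` list of logicals).
#' @param out_dir Output directory (created; one directory per run).
#' @param stages Named logical list to toggle stages, e.g.
#'   `list(signatures = FALSE)`. All enabled by default.
#' @return The report, invisibly (also written to `report.json`).
#' @export
run_pipeline <- function(config, out_dir, stages = list()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  enabled <- function(s) !identical(stages[[s]], FALSE)
  manifest <- file.path(out_dir, "MANIFEST")
  writeLines(character(0), manifest)
  done <- function(s) cat(s, "\n", sep = "", file = manifest, append = TRUE)
  report <- list(package = "pirnaphase",
                 version = as.character(utils::packageVersion("pirnaphase")),
                 seed = config$seed,
                 config = unclass(config))
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (!enabled(name)) return(invisible(NULL))
    pp_log("stage: ", name)
    ok <- tryCatch({fun(); TRUE}, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    if (ok) done(name)
  }

  run_stage("simulate", function() {
    gen <- build_genome(config)
    truth <- simulate_biogenesis(config, gen)
    reads <- emit_reads(truth, gen, config)
    Biostrings::writeXStringSet(gen$genome,
                                file.path(out_dir, "genome.fa"))
    Biostrings::writeXStringSet(gen$rrna, file.path(out_dir, "rrna.fa"))
    Biostrings::writeXStringSet(gen$spikes, file.path(out_dir, "spikes.fa"))
    write_annotation_bed(gen$annotation,
                         file.path(out_dir, "annotation.bed"))
    write_tsv(truth$small, file.path(out_dir, "truth_small_species.tsv"))
    write_tsv(truth$long, file.path(out_dir, "truth_long_species.tsv"))
    for (i in seq_along(reads$small_libs)) {
      write_fastq(reads$small_libs[[i]]$reads,
                  file.path(out_dir, sprintf("smallrna_lib%d.fastq", i)))
      write_tsv(reads$small_libs[[i]]$truth,
                file.path(out_dir, sprintf("smallrna_lib%d.truth.tsv", i)))
    }
    for (i in seq_along(reads$long_libs)) {
      write_fastq(reads$long_libs[[i]]$reads,
                  file.path(out_dir, sprintf("longrna_lib%d.fastq", i)))
    }
    state$gen <- gen
    state$truth <- truth
    state$reads <- reads
    report$simulate <<- list(
      small_species = nrow(truth$small),
      long_species = nrow(truth$long),
      cut_sites = length(truth$cut_sites)
    )
  })

  run_stage("preprocess", function() {
    libs <- lapply(seq_along(state$reads$small_libs), function(i) {
      parsed <- parse_small_rna_reads(state$reads$small_libs[[i]]$reads)
      species <- deduplicate(parsed)
      species <- classify_reads(species, state$gen$rrna, state$gen$spikes)
      write_tsv(species,
                file.path(out_dir, sprintf("species_lib%d.tsv", i)))
      list(parsed_rate = mean(parsed$status == "ok"), species = species)
    })
    state$species_libs <- lapply(libs, `[[`, "species")
    report$preprocess <<- list(
      parse_rate = vapply(libs, `[[`, numeric(1), "parsed_rate"),
      species_per_lib = vapply(state$species_libs, nrow, integer(1))
    )
  })

  run_stage("map", function() {
    ann <- state$gen$annotation
    state$assigned_libs <- lapply(seq_along(state$species_libs),
                                  function(i) {
      sp <- state$species_libs[[i]]
      retained <- sp[sp$class == "retained", , drop = FALSE]
      aln <- align_ungapped(retained$sequence, state$gen$genome)
      aln$count <- retained$count[match(aln$sequence, retained$sequence)]
      aln <- assign_feature(aln, ann)
      write_tsv(aln, file.path(out_dir, sprintf("alignments_lib%d.tsv", i)))
      aln
    })
    locus_sp <- lapply(state$assigned_libs, function(aln) {
      sub <- aln[aln$feature == "suste_like" & aln$strand == "+", ,
                 drop = FALSE]
      sub <- sub[!duplicated(sub$sequence), , drop = FALSE]
      data.frame(sequence = sub$sequence, count = sub$count)
    })
    pooled <- do.call(rbind, locus_sp)
    comp <- if (nrow(pooled)) nt_composition(pooled) else NULL
    prof <- length_profile(
      data.frame(sequence = pooled$sequence, count = pooled$count),
      length_range = c(15L, 35L))
    write_tsv(prof, file.path(out_dir, "length_profile_suste.tsv"))
    state$composition <- comp
    report$map <<- list(
      aligned_species = vapply(state$assigned_libs, function(a) {
        length(unique(a$sequence))
      }, integer(1)),
      u1_percent = if (!is.null(comp)) 100 * comp$per_position["1", "T"]
                   else NA,
      a10_percent = if (!is.null(comp)) 100 * comp$per_position["10", "T"]
                    else NA,
      background_u_percent = if (!is.null(comp)) 100 * comp$background[["T"]]
                             else NA
    )
  })

  run_stage("signatures", function() {
    gen <- state$gen
    long_sets <- lapply(seq_along(state$reads$long_libs), function(i) {
      reads <- strip_degenerate_block(state$reads$long_libs[[i]]$reads)
      tab <- table(reads)
      aln <- align_ungapped(names(tab), gen$genome, max_tail = 0L)
      aln <- aln[!duplicated(aln$sequence), , drop = FALSE]  # unique best
      aln$count <- as.integer(tab[aln$sequence])
      merge_long_rnas(aln)
    })
    prepre_sets <- lapply(long_sets, function(ls) {
      identify_prepre(ls, gen$layout$locus, gen$layout$insertion)
    })
    guide_sets <- lapply(state$assigned_libs, function(aln) {
      g <- aln[aln$feature == "hoppel_like" & aln$strand == "-", ,
               drop = FALSE]
      data.frame(chrom = g$chrom, strand = g$strand,
                 five_prime = g$five_prime, count = g$count)
    })

    trig_spectra <- list()
    for (g in guide_sets) for (p in prepre_sets) {
      trig_spectra[[length(trig_spectra) + 1L]] <- overlap_spectrum(p, g)
    }
    trig_z <- permutation_z(trig_spectra)

    # Genic negatives: sense decay long RNAs vs antisense genic small RNAs.
    genic_long_sets <- lapply(long_sets, function(ls) {
      ls[ls$chrom == "chr2" & ls$length >= 200L, , drop = FALSE]
    })
    genic_guides <- lapply(state$assigned_libs, function(aln) {
      g <- aln[aln$feature_class == "genic" & aln$chrom == "chr2", ,
               drop = FALSE]
      data.frame(chrom = g$chrom, strand = g$strand,
                 five_prime = g$five_prime, count = g$count)
    })
    genic_spectra <- list()
    for (g in genic_guides) for (p in genic_long_sets) {
      genic_spectra[[length(genic_spectra) + 1L]] <- overlap_spectrum(p, g)
    }
    genic_z <- permutation_z(genic_spectra)

    pirna_sets <- lapply(state$assigned_libs, function(aln) {
      s <- aln[aln$feature == "suste_like" & aln$strand == "+", ,
               drop = FALSE]
      data.frame(chrom = s$chrom, strand = s$strand,
                 five_prime = s$five_prime, count = s$count)
    })
    meta <- phasing_metaplot(prepre_sets, pirna_sets)
    period <- NULL
    if (!meta$all_zero) {
      ac <- autocorrelate(meta)
      period <- tryCatch(estimate_period(ac),
                         error = function(e) NULL)
      write_tsv(data.frame(lag = as.integer(names(ac)), r = ac),
                file.path(out_dir, "autocorrelation.tsv"))
    }
    write_tsv(data.frame(position = seq_len(meta$L) - 1L,
                         median = meta$median, q25 = meta$q25,
                         q75 = meta$q75),
              file.path(out_dir, "metaplot.tsv"))
    spec_df <- data.frame(
      offset = 0:20,
      trigger = Reduce(`+`, lapply(trig_spectra, `[[`, "counts")),
      genic = Reduce(`+`, lapply(genic_spectra, `[[`, "counts")))
    write_tsv(spec_df, file.path(out_dir, "overlap_spectra.tsv"))

    report$signatures <<- list(
      n_prepre = vapply(prepre_sets, nrow, integer(1)),
      z10_trigger = trig_z$z_mean,
      p10_trigger = trig_z$p_mean,
      z10_trigger_pooled = trig_z$z_pooled,
      z10_genic = genic_z$z_mean,
      z10_genic_pooled = genic_z$z_pooled,
      phase_period_nt = if (!is.null(period)) period$period else NA,
      phase_period_r = if (!is.null(period)) period$r else NA,
      phase_period_harmonic = if (!is.null(period)) period$harmonic else NA
    )
  })

  run_stage("abundance", function() {
    per_lib <- lapply(seq_along(state$species_libs), function(i) {
      sp <- state$species_libs[[i]]
      spikes <- sp$count[sp$class == "spikein"]
      spike_counts <- numeric(length(state$gen$spikes))
      names(spike_counts) <- names(state$gen$spikes)
      obs <- sp[sp$class == "spikein", , drop = FALSE]
      spike_counts[obs$spike_id] <- obs$count
      calib <- spike_calibration(spike_counts,
                                 config$spike_molecules,
                                 config$total_rna_pg)
      aln <- state$assigned_libs[[i]]
      trig_reads <- sum(aln$weight[aln$feature == "hoppel_like" &
                                     aln$strand == "-"])
      suste_reads <- sum(aln$weight[aln$feature == "suste_like"])
      c(trigger = absolute_abundance(trig_reads, calib),
        suste = absolute_abundance(suste_reads, calib))
    })
    ab <- do.call(rbind, per_lib)
    report$abundance <<- list(
      trigger_pirna_per_10pg = mean(ab[, "trigger"]),
      suste_pirna_per_10pg = mean(ab[, "suste"])
    )
  })

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(report)
}

#' Read a pipeline run configuration from YAML
#'
#' Unknown keys are rejected; known keys override [sim_config()] defaults.
#'
#' @param path YAML file path.
#' @return A [sim_config()].
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(sim_config, vals)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
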