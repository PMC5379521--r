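# End-to-end orchestration: write a scenario bundle to disk, run every
# stage over a directory of inputs, and capture a provenance manifest.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a scenario bundle to a directory
#'
#' Emits the on-disk dataset consumed by [run_full()]: genome.fa,
#' transcripts_A.fa, transcripts_B.fa, reads_lib1.fa (collapsed, `_xN`
#' headers), reference_mirnas.fa, exclusion_rrna.fa, variants.vcf,
#' groups.tsv, gene_models.tsv, degradome.tsv, truth/*.tsv and config.json.
#'
#' @param bundle a "scenario_bundle" from [make_scenario()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_scenario <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  write_fasta(bundle$genome, file.path(dir, "genome.fa"))
  write_fasta(bundle$transcripts_a, file.path(dir, "transcripts_A.fa"))
  write_fasta(bundle$transcripts_b, file.path(dir, "transcripts_B.fa"))
  if (length(bundle$reference_mirnas)) {
    write_fasta(bundle$reference_mirnas, file.path(dir, "reference_mirnas.fa"))
  }
  write_fasta(bundle$exclusion_sets$rrna, file.path(dir, "exclusion_rrna.fa"))
  reads <- bundle$reads
  ids <- sprintf("r%04d_x%d", seq_len(nrow(reads)), reads$count)
  write_fasta(stats::setNames(reads$seq, ids), file.path(dir, "reads_lib1.fa"))
  # VCF
  con <- file(file.path(dir, "variants.vcf"), "w")
  writeLines(c("##fileformat=VCFv4.2",
               "##source=mirtarsnp synthetic scenario",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", bundle$samples$sample),
                     collapse = "\t")), con)
  vp <- bundle$variant_positions
  for (i in seq_len(nrow(vp))) {
    writeLines(paste(c(vp$chrom[i], vp$pos[i], ".", vp$ref[i], vp$alt[i],
                       ".", "PASS", ".", "GT", bundle$genotypes[i, ]),
                     collapse = "\t"), con)
  }
  close(con)
  write_tsv(bundle$samples, file.path(dir, "groups.tsv"))
  write_tsv(bundle$gene_models, file.path(dir, "gene_models.tsv"))
  write_tsv(bundle$degradome_tags, file.path(dir, "degradome.tsv"))
  # hairpin annotation as GFF3 (precursor + mature features)
  gff <- file(file.path(dir, "mirnas.gff3"), "w")
  writeLines("##gff-version 3", gff)
  hp <- bundle$hairpins
  for (i in seq_len(nrow(hp))) {
    writeLines(paste(hp$chrom[i], "mirtarsnp", "miRNA_primary_transcript",
                     hp$start[i] + 1L, hp$end[i], ".", hp$strand[i], ".",
                     paste0("ID=", hp$id[i]), sep = "\t"), gff)
    m <- nchar(hp$mature_seq[i])
    if (hp$strand[i] == "+") {
      ms <- hp$start[i] + hp$mature_offset[i] + 1L
      me <- ms + m - 1L
    } else {
      me <- hp$end[i] - hp$mature_offset[i]
      ms <- me - m + 1L
    }
    writeLines(paste(hp$chrom[i], "mirtarsnp", "miRNA", ms, me, ".",
                     hp$strand[i], ".", paste0("ID=", hp$id[i], "_mature"),
                     sep = "\t"), gff)
  }
  close(gff)
  write_tsv(bundle$truth$hairpins[, setdiff(names(bundle$truth$hairpins),
                                            "precursor")],
            file.path(dir, "truth", "hairpins.tsv"))
  write_tsv(bundle$truth$sites, file.path(dir, "truth", "sites.tsv"))
  write_tsv(bundle$truth$events, file.path(dir, "truth", "events.tsv"))
  write_tsv(bundle$truth$degradome, file.path(dir, "truth", "degradome.tsv"))
  cfg <- bundle$config
  cfg$params <- unclass(cfg$params)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Run the full pipeline over a scenario directory
#'
#' Stages, in order: miRNA discovery from collapsed reads, target scan,
#' locus-class nucleotide diversity with permutation p-values, SNP-impact
#' diff with orthologue validation and group-unique target calls, and
#' degradome confirmation. Results are written as TSVs to `out_dir`
#' together with a manifest (inputs, digests, seed, row counts). A missing
#' input aborts before any stage runs.
#'
#' @param input_dir directory as written by [write_scenario()].
#' @param out_dir output directory.
#' @param seed seed for the stochastic stages (diversity permutations).
#' @param n_perm permutations per diversity class.
#' @param params [score_params()].
#' @param group_a,group_b group labels.
#' @return invisible list with all stage results (loci, expression,
#'   interactions, diversity, impact, degradome_calls, summary).
#' @export
run_full <- function(input_dir, out_dir, seed = 1L, n_perm = 199L,
                     params = score_params(), group_a = "A", group_b = "B") {
  need <- c("genome.fa", "transcripts_A.fa", "transcripts_B.fa",
            "reads_lib1.fa", "reference_mirnas.fa", "exclusion_rrna.fa",
            "variants.vcf", "groups.tsv", "gene_models.tsv", "degradome.tsv")
  paths <- file.path(input_dir, need)
  missing <- need[!file.exists(paths)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  genome <- read_fasta(file.path(input_dir, "genome.fa"))
  transcripts_a <- read_fasta(file.path(input_dir, "transcripts_A.fa"))
  transcripts_b <- read_fasta(file.path(input_dir, "transcripts_B.fa"))
  reference <- read_fasta(file.path(input_dir, "reference_mirnas.fa"))
  exclusion <- list(rrna = read_fasta(file.path(input_dir, "exclusion_rrna.fa")))
  reads <- read_collapsed_reads(file.path(input_dir, "reads_lib1.fa"),
                                "header_xN", library_id = "lib1")
  groups <- utils::read.table(file.path(input_dir, "groups.tsv"),
                              header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  gene_models <- utils::read.table(file.path(input_dir, "gene_models.tsv"),
                                   header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE)
  variants <- read_variants(file.path(input_dir, "variants.vcf"),
                            stats::setNames(groups$group, groups$sample))
  tags <- utils::read.table(file.path(input_dir, "degradome.tsv"),
                            header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  family_classes <- stats::setNames(
    ifelse(grepl("known", names(reference)), "known", "conserved"),
    names(reference))

  # stage 1: discovery
  disc <- discover_mirnas(reads, genome, reference,
                          exclusion_sets = exclusion,
                          family_classes = family_classes)
  write_tsv(disc$loci, file.path(out_dir, "mirna_loci.tsv"))
  write_tsv(disc$expression, file.path(out_dir, "expression.tsv"))

  # stage 2: baseline target scan (group A)
  interactions <- list()
  for (r in seq_len(nrow(disc$loci))) {
    for (tid in names(transcripts_a)) {
      s <- find_sites(disc$loci$mature_seq[r], transcripts_a[[tid]], params,
                      mirna_id = disc$loci$id[r], transcript_id = tid)
      if (nrow(s)) interactions[[length(interactions) + 1L]] <- s
    }
  }
  interactions <- if (length(interactions)) do.call(rbind, interactions)
    else empty_interactions()
  write_tsv(interactions, file.path(out_dir, "interactions_A.tsv"))

  # stage 3: diversity by locus class
  genome_lengths <- stats::setNames(nchar(genome), names(genome))
  mirna_classes <- stats::setNames(
    ifelse(disc$loci$class_label %in% c("conserved", "known"),
           "conserved_known", "specific"), disc$loci$id)
  classes <- classify_loci(disc$loci, interactions, gene_models,
                           genome_lengths, mirna_classes = mirna_classes)
  diversity <- diversity_table(classes, variants, genome_lengths,
                               n_perm = n_perm, seed = seed)
  write_tsv(diversity, file.path(out_dir, "diversity.tsv"))

  # stage 4: SNP impact and group-unique targets
  impact <- snp_impact_analysis(disc$loci, transcripts_a, gene_models,
                                variants, group_a, group_b, params,
                                ortholog_seqs = transcripts_b)
  write_tsv(impact$deltas, file.path(out_dir, "deltas.tsv"))
  write_tsv(impact$unique_targets$counts,
            file.path(out_dir, "unique_targets.tsv"))

  # stage 5: degradome confirmation of group-A interactions
  profiles <- map_tags(tags, transcripts_a)
  calls <- list()
  for (r in seq_len(nrow(interactions))) {
    prof <- profiles[[interactions$transcript_id[r]]]
    if (is.null(prof)) next
    cc <- confirm_interaction(interactions[r, ], prof)
    if (!is.null(cc)) calls[[length(calls) + 1L]] <- cc
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(transcript_id = character(0), mirna_id = character(0),
               position = integer(0), count = numeric(0),
               category = integer(0), p_value = numeric(0),
               significant = logical(0), stringsAsFactors = FALSE)
  write_tsv(calls, file.path(out_dir, "degradome_calls.tsv"))

  summary <- data.frame(
    metric = c("reads_total", "reads_kept", "loci_annotated",
               "loci_conserved_known", "loci_specific_with_star",
               "loci_specific_candidate", "interactions_A",
               "deltas_conserved", "deltas_disrupted", "deltas_created",
               "a_unique_targets", "b_unique_targets",
               "degradome_calls_category0_significant"),
    value = c(nrow(reads), nrow(reads) - sum(disc$filter_report$n),
              nrow(disc$loci),
              sum(disc$loci$class_label %in% c("conserved", "known")),
              sum(disc$loci$class_label == "specific_with_star"),
              sum(disc$loci$class_label == "specific_candidate"),
              nrow(interactions),
              sum(impact$deltas$status == "conserved"),
              sum(impact$deltas$status == "disrupted"),
              sum(impact$deltas$status == "created"),
              impact$unique_targets$counts$n_unique[1],
              impact$unique_targets$counts$n_unique[2],
              sum(calls$category == 0L & calls$significant)),
    stringsAsFactors = FALSE)
  write_tsv(summary, file.path(out_dir, "summary.tsv"))

  manifest <- list(
    tool = "mirtarsnp", version = "0.1.0",
    seed = seed, n_perm = n_perm,
    params = unclass(params),
    inputs = as.list(stats::setNames(unname(tools::md5sum(paths)), need)),
    rows = list(loci = nrow(disc$loci), interactions = nrow(interactions),
                diversity = nrow(diversity), deltas = nrow(impact$deltas),
                degradome_calls = nrow(calls)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(loci = disc$loci, expression = disc$expression,
                 interactions = interactions, diversity = diversity,
                 impact = impact, degradome_calls = calls,
                 summary = summary))
}
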