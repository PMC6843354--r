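#' Run a pipeline stage
#'
#' Thin driver tying the analysis modules into a file-based pipeline. Each
#' stage reads the inputs named in the configuration, writes its output
#' tables under `out_dir`, and records a machine-readable run manifest
#' (stage, configuration, input checksums, package version). Stages are
#' deterministic: rerunning with unchanged inputs reproduces every output
#' byte for byte.
#'
#' Configuration keys (YAML file or list): `out_dir`, `seed`, `ppm_tol`,
#' `protein_fasta`, `protein_start`, `digest_tsv`, `peaklists` (vector of
#' CSV paths), `hdx_csv`, `structure_pdb`, `missed`, plus any
#' [scenario_config()] field for the simulate stage.
#'
#' @param stage One of `"simulate"`, `"digest"`, `"annotate"`,
#'   `"xlsearch"`, `"xlquant"`, `"hdx"`, `"restraints"`, `"all"`.
#' @param config Path to a YAML config file, or an equivalent named list.
#' @return Invisibly, a list of output paths written by the stage.
#' @export
run_stage <- function(stage, config) {
  stages <- c("simulate", "digest", "annotate", "xlsearch", "xlquant",
              "hdx", "restraints", "all")
  if (!stage %in% stages) {
    stop("unknown stage '", stage, "'; usage: run_stage(<stage>, config) with stage in: ",
         paste(stages, collapse = ", "))
  }
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  out_dir <- cfg$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  need <- function(key) {
    p <- cfg[[key]]
    if (is.null(p)) stop("stage '", stage, "' requires config key '", key, "'")
    missing <- p[!file.exists(p)]
    if (length(missing) > 0) stop("input file not found: ", paste(missing, collapse = ", "))
    p
  }
  outputs <- character(0)
  inputs <- character(0)

  if (stage %in% c("simulate", "all")) {
    sc_keys <- intersect(names(cfg), names(formals(scenario_config)))
    sc <- do.call(scenario_config, cfg[sc_keys])
    scen <- simulate_scenario(file.path(out_dir, "scenario"), sc)
    outputs <- c(outputs, unlist(scen$paths))
    if (stage == "all") {
      cfg$protein_fasta <- scen$paths$protein_fasta
      cfg$digest_tsv <- scen$paths$digest_tsv
      cfg$peaklists <- scen$paths$peaks
      cfg$hdx_csv <- scen$paths$hdx_csv
      cfg$structure_pdb <- scen$paths$fold_pdb
      cfg$protein_start <- sc$protein_start
    }
  }

  if (stage %in% c("digest", "all")) {
    fa <- need("protein_fasta"); inputs <- c(inputs, fa)
    prot <- read_fasta(fa, "protein")[[1]]
    dg <- trypsin_digest(prot, digest_config(missed = cfg$missed %||% 2L),
                         start_pos = cfg$protein_start %||% 1L)
    p <- file.path(out_dir, "digest.tsv")
    write_digest_tsv(dg, p)
    outputs <- c(outputs, p)
    cfg$digest_tsv <- cfg$digest_tsv %||% p
  }

  if (stage == "annotate") {
    pk <- need("peaklists")[1]; inputs <- c(inputs, pk)
    peaks <- read_peaklist(pk)
    sp <- lapply(cfg$species, function(s) species_model(s$name, s$base_mass))
    ann <- annotate_intact(peaks, sp, ppm_tol = cfg$ppm_tol %||% 5)
    p <- file.path(out_dir, "intact_annotation.tsv")
    utils::write.table(ann, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, p)
  }

  if (stage %in% c("xlsearch", "all")) {
    dgp <- need("digest_tsv"); inputs <- c(inputs, dgp)
    dg <- utils::read.table(dgp, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    lib <- build_library(dg, linkers = xl_linkers(),
                         types = c("inter", "loop", "mono"))
    pks <- need("peaklists"); inputs <- c(inputs, pks)
    id_paths <- character(0)
    for (pk in pks) {
      ids <- site_localization_report(
        match_peaks(read_peaklist(pk), lib, ppm_tol = cfg$ppm_tol %||% 5))
      p <- file.path(out_dir, paste0("ids_", basename(tools::file_path_sans_ext(pk)), ".tsv"))
      write_identifications_tsv(ids, p)
      id_paths <- c(id_paths, p)
    }
    outputs <- c(outputs, id_paths)
    cfg$identifications <- id_paths
  }

  if (stage %in% c("xlquant", "all")) {
    pks <- need("peaklists"); inputs <- c(inputs, pks)
    dgp <- need("digest_tsv")
    dg <- utils::read.table(dgp, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    lib <- build_library(dg, linkers = xl_linkers(), types = "inter")
    rows <- list()
    for (r in seq_along(pks)) {
      peaks <- read_peaklist(pks[r])
      prs <- partition(pair_doublets(peaks))
      if (nrow(prs) == 0) next
      ids <- match_peaks(data.frame(mass = prs$light_mass,
                                    intensity = prs$light_intensity),
                         lib[lib$form == "light", , drop = FALSE],
                         ppm_tol = cfg$ppm_tol %||% 5)
      best <- ids[ids$rank == 1, , drop = FALSE]
      m <- match(seq_len(nrow(prs)), best$peak)
      prs$conjugate <- ifelse(is.na(m), NA_character_,
                              paste0(best$seq1[m], "(", best$start1[m], "-", best$end1[m], ")x",
                                     best$seq2[m], "(", best$start2[m], "-", best$end2[m], ")"))
      prs$linker <- ifelse(is.na(m), NA_character_, best$linker[m])
      prs$replicate <- r
      rows[[length(rows) + 1L]] <- prs[!is.na(prs$conjugate), , drop = FALSE]
    }
    quant <- do.call(rbind, rows)
    agg <- differential_report(aggregate_replicates(quant))
    p <- file.path(out_dir, "xl_partition.tsv")
    utils::write.table(agg, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, p)
  }

  if (stage %in% c("hdx", "all")) {
    hp <- need("hdx_csv"); inputs <- c(inputs, hp)
    fa <- need("protein_fasta")
    prot <- read_fasta(fa, "protein")[[1]]
    cent <- utils::read.csv(hp, stringsAsFactors = FALSE)
    upt <- peptide_uptake(cent)
    rdr <- residue_dr_table(upt, prot, start_pos = cfg$protein_start %||% 1L)
    diffp <- hdx_differential(rdr[rdr$state == "free", ],
                              rdr[rdr$state == "complex", ])
    p1 <- file.path(out_dir, "residue_dr.tsv")
    p2 <- file.path(out_dir, "ddr_matrix.csv")
    p3 <- file.path(out_dir, "active_residues.txt")
    utils::write.table(rdr, p1, sep = "\t", quote = FALSE, row.names = FALSE)
    wide <- stats::reshape(diffp[, c("residue", "time", "ddr")],
                           idvar = "residue", timevar = "time",
                           direction = "wide")
    utils::write.csv(wide, p2, row.names = FALSE, quote = FALSE)
    export_active_residues(diffp, path = p3)
    outputs <- c(outputs, p1, p2, p3)
  }

  if (stage %in% c("restraints", "all")) {
    idp <- if (!is.null(cfg$identifications)) cfg$identifications[1] else need("identifications")
    inputs <- c(inputs, idp)
    ids <- utils::read.table(idp, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    ids <- ids[ids$rank == 1 & ids$type %in% c("inter", "loop", "peptide_dna"), , drop = FALSE]
    rs <- xl_to_restraints(ids)
    p1 <- file.path(out_dir, "restraints.tsv")
    export_restraints(rs, p1, "tsv")
    outputs <- c(outputs, p1)
    if (!is.null(cfg$structure_pdb)) {
      rep_ <- measure_restraints(cfg$structure_pdb, rs)
      p2 <- file.path(out_dir, "restraint_satisfaction.tsv")
      utils::write.table(rep_$members, p2, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      outputs <- c(outputs, p2)
    }
  }

  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("xlhdx")),
    config = cfg[!vapply(cfg, is.function, logical(1))],
    input_md5 = as.list(tools::md5sum(unique(inputs))),
    output_md5 = as.list(tools::md5sum(unique(outputs)))
  )
  mp <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(unique(outputs), mp))
}
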