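#' Read a simulation scenario configuration
#'
#' YAML file whose keys match [sim_params()] argument names; unknown keys are
#' rejected.
#'
#' @param path path to a YAML config file.
#' @return A [sim_params()] object.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(sim_params))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(sim_params, cfg)
}

#' Write / read trajectory snapshots as TSV
#'
#' Snapshot table columns: `generation`, `individual`, `location`,
#' `mating_freq`, `neutral_freq`. [write_trajectory_tsv()] also writes a
#' sidecar `<path>.meta.yaml` with the seed and scenario parameters.
#'
#' @param traj an `hz_trajectory` from [run_simulation()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(traj, path) {
  stopifnot(inherits(traj, "hz_trajectory"))
  write.table(traj$snapshots, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  meta <- traj$params
  meta$range_a <- as.list(meta$range_a)
  meta$range_b <- as.list(meta$range_b)
  meta$extinct <- traj$extinct
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_trajectory_tsv
#' @return For [read_snapshot_tsv()], the snapshot data frame.
#' @export
read_snapshot_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t")
}

#' Write per-replicate cline summaries as TSV
#'
#' One row per replicate and scenario: scenario parameters, seed, centers,
#' widths, movement class, displacement and flags — sufficient to recompute
#' every grid summary.
#'
#' @param results list of [run_scenario()] results.
#' @param path output TSV path.
#' @return The combined data frame, invisibly.
#' @export
write_scenario_tsv <- function(results, path) {
  rows <- do.call(rbind, lapply(results, function(res) {
    cbind(n_mating_loci = res$scenario$n_mating_loci,
          pref_ratio = res$scenario$pref_ratio,
          dominance = res$scenario$dominance,
          res$replicates)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}

#' Write / read a diagnostic genotype matrix as TSV
#'
#' Rows are individuals, columns are loci; column names carry the region
#' label as a `chr1A_`/`chr20_` prefix; missing genotypes are `NA`. An
#' optional `class` column (cross class) is stored first when present.
#'
#' @param geno a [diagnostic_genotypes()].
#' @param path TSV path.
#' @return `path` ([write_genotype_tsv()]) or a [diagnostic_genotypes()]
#'   ([read_genotype_tsv()]), invisibly for the writer.
#' @export
write_genotype_tsv <- function(geno, path) {
  stopifnot(inherits(geno, "diagnostic_genotypes"))
  df <- as.data.frame(geno$dosage)
  df <- cbind(individual = rownames(geno$dosage) %||%
                as.character(seq_len(nrow(geno$dosage))), df)
  if (!is.null(geno$class)) df <- cbind(df[1], class = geno$class, df[-1])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  cls <- if ("class" %in% names(df)) df$class else NULL
  ids <- if ("individual" %in% names(df)) df$individual else NULL
  locus_cols <- grep("^chr(1A|20)_", names(df), value = TRUE)
  if (length(locus_cols) == 0) stop("no chr1A_/chr20_ locus columns found")
  dosage <- as.matrix(df[locus_cols])
  storage.mode(dosage) <- "integer"
  rownames(dosage) <- ids
  region <- sub("_.*$", "", locus_cols)
  diagnostic_genotypes(dosage, region, cls)
}

#' Read diagnostic genotypes from a VCF file
#'
#' Restricted to a user-supplied table of diagnostic sites. Dosages count
#' personata-type alleles, so the table must say which allele (REF or ALT)
#' is the personata one at each site. Requires the `vcfR` package.
#'
#' @param path VCF path (plain or bgzipped).
#' @param sites data frame with columns `chrom`, `pos`, `region` (`"chr1A"`
#'   or `"chr20"`) and `personata_allele` (`"REF"` or `"ALT"`).
#' @return A [diagnostic_genotypes()] (individuals = VCF samples).
#' @export
read_diagnostic_vcf <- function(path, sites) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_diagnostic_vcf requires the vcfR package")
  }
  stopifnot(all(c("chrom", "pos", "region", "personata_allele") %in%
                  names(sites)))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  key <- paste(fix[, "CHROM"], fix[, "POS"])
  want <- paste(sites$chrom, sites$pos)
  idx <- match(want, key)
  if (anyNA(idx)) {
    stop(sum(is.na(idx)), " diagnostic site(s) not found in the VCF")
  }
  gt <- vcfR::extract.gt(v, element = "GT")[idx, , drop = FALSE]
  # ALT dosage from the genotype string; any ploidy separator accepted
  alt_dosage <- function(g) {
    ifelse(is.na(g) | g %in% c(".", "./.", ".|."), NA_integer_,
           vapply(strsplit(g, "[/|]"), function(a) {
             a <- suppressWarnings(as.integer(a))
             if (anyNA(a)) NA_integer_ else sum(a > 0L)
           }, integer(1)))
  }
  dos <- apply(gt, 2, alt_dosage)
  dos <- matrix(dos, nrow = nrow(gt),
                dimnames = list(NULL, colnames(gt)))
  flip <- sites$personata_allele == "REF"
  dos[flip, ] <- 2L - dos[flip, ]
  dosage <- t(dos)
  colnames(dosage) <- paste0(sites$region, "_", seq_along(sites$region))
  diagnostic_genotypes(dosage, sites$region)
}
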