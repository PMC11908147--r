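## Configuration loading, trajectory serialization, haplotype export.

config_sim_keys <- c("N", "ploidy", "mu", "rho", "s", "generations", "L",
                     "seed", "selfing_allowed", "snapshot_generations")
config_sweep_keys <- c("N", "ploidy", "mu", "rho", "s", "replicates",
                       "generations", "L", "base_seed",
                       "aggregation_generation", "selfing_allowed",
                       "pod_window", "pod_freq_threshold",
                       "pod_stability_threshold", "sweep")

#' Load a simulation or sweep configuration from YAML
#'
#' A config with any multi-valued parameter, a `replicates` field or
#' `sweep: true` is interpreted as a sweep ([sweep_config()]); otherwise
#' as a single replicate ([sim_params()]).  Unknown keys are rejected by
#' name; every defaulted field is reported via [message()].
#'
#' @param path Path to a YAML file.
#' @return A `pod_params` or `pod_sweep_config` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg) || is.null(names(cfg)))
    stop("config must be a YAML mapping of parameter: value", call. = FALSE)
  # YAML 1.1 reads a bare `N:` key as the boolean FALSE; map it back
  names(cfg)[names(cfg) %in% c("FALSE", "false")] <- "N"
  required <- c("N", "ploidy", "mu", "rho", "s", "generations")
  missing_req <- setdiff(required, names(cfg))
  if (length(missing_req))
    stop("config is missing required field(s): ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  is_sweep <- isTRUE(cfg$sweep) || "replicates" %in% names(cfg) ||
    any(lengths(cfg[c("N", "ploidy", "mu", "rho", "s")]) > 1L)
  allowed <- if (is_sweep) config_sweep_keys else config_sim_keys
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg$sweep <- NULL
  maker <- if (is_sweep) sweep_config else sim_params
  defaulted <- setdiff(names(formals(maker)), names(cfg))
  if (length(defaulted))
    message("applying defaults for: ", paste(defaulted, collapse = ", "))
  do.call(maker, cfg)
}

#' Write a trajectory to a tab-separated file
#'
#' The header is a block of `#`-prefixed lines recording the package
#' version, seed and full parameter set, followed by the per-generation
#' statistics table.  [read_stats()] restores the table (and the header
#' metadata as attributes) losslessly.
#'
#' @param sim A `pod_sim` object, or a trajectory data frame.
#' @param path Output file path.
#' @param params Parameters to record in the header (taken from `sim` when
#'   it is a `pod_sim`).
#' @return `path`, invisibly.
#' @export
write_stats <- function(sim, path, params = NULL) {
  if (inherits(sim, "pod_sim")) {
    params <- sim$params
    trajectory <- sim$trajectory
  } else {
    trajectory <- sim
  }
  stopifnot(is.data.frame(trajectory))
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("podsim"))
  writeLines(sprintf("# podsim %s trajectory", ver), con)
  if (!is.null(params)) {
    for (nm in c("N", "ploidy", "L", "mu", "rho", "s", "generations",
                 "selfing_allowed"))
      writeLines(sprintf("# %s: %s", nm, format(params[[nm]], digits = 17)),
                 con)
    writeLines(sprintf("# seed: %s",
                       if (is.null(params$seed)) "NA" else params$seed), con)
  }
  write.table(trajectory, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a trajectory written by [write_stats()]
#'
#' @param path Path to a trajectory file.
#' @return The trajectory data frame, with header metadata (version,
#'   parameter lines) in `attr(, "header")`.  A file missing any core
#'   statistics column is rejected with the offending line number.
#' @export
read_stats <- function(path) {
  if (!file.exists(path))
    stop("trajectory file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  n_comment <- 0L
  while (n_comment < length(lines) &&
         startsWith(lines[n_comment + 1L], "#"))
    n_comment <- n_comment + 1L
  if (n_comment == length(lines))
    stop("parse error at line ", n_comment,
         ": no column header found", call. = FALSE)
  header_line <- n_comment + 1L
  cols <- strsplit(lines[header_line], "\t", fixed = TRUE)[[1L]]
  missing_cols <- setdiff(traj_colnames, cols)
  if (length(missing_cols))
    stop("parse error at line ", header_line, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  df$generation <- as.integer(df$generation)
  df$n_segregating <- as.integer(df$n_segregating)
  df$n_substitutions <- as.integer(df$n_substitutions)
  attr(df, "header") <- sub("^# ?", "", lines[seq_len(n_comment)])
  df
}

#' Export population haplotypes as an ms-style matrix or minimal VCF
#'
#' `ms` format: a `segsites:` line, a `positions:` line with segregating
#' positions scaled to `[0, 1)`, then one 0/1 row per haplotype
#' (`ploidy * N` rows).  `vcf` format: one record per segregating
#' mutation, 1-based `POS` (internal coordinates are 0-based; converted at
#' this boundary only), synthetic `REF`/`ALT` alleles, `INFO` field
#' `S=<selection coefficient>`, and per-individual unphased `GT` fields
#' carrying `ploidy` alleles in copy order (e.g. `0/0/0/1`).
#'
#' @param population A `pod_population`.
#' @param path Output file path.
#' @param format `"ms"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
export_haplotypes <- function(population, path, format = c("ms", "vcf")) {
  stopifnot(inherits(population, "pod_population"))
  format <- match.arg(format)
  reg <- population$registry
  freqs <- segregating_frequencies(population)
  ids <- as.integer(names(freqs))
  ids <- ids[order(reg$pos[ids], ids)]
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "ms") {
    writeLines(c("//", sprintf("segsites: %d", length(ids))), con)
    writeLines(paste(c("positions:",
                       sprintf("%.8f", reg$pos[ids] / population$L)),
                     collapse = " "), con)
    rows <- vapply(population$haplotypes, function(h)
      paste(as.integer(ids %in% h), collapse = ""), character(1))
    writeLines(rows, con)
  } else {
    p <- population$ploidy
    samples <- sprintf("ind%d", seq_len(population$N))
    writeLines(c(
      "##fileformat=VCFv4.2",
      sprintf("##source=podsim %s",
              as.character(utils::packageVersion("podsim"))),
      sprintf("##contig=<ID=chr1,length=%d>", as.integer(population$L)),
      "##INFO=<ID=S,Number=1,Type=Float,Description=\"Selection coefficient (fully recessive)\">",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype, one allele per chromosome copy\">",
      "##reference=synthetic (REF/ALT alleles are placeholders)",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", samples), collapse = "\t")), con)
    for (id in ids) {
      gts <- vapply(seq_len(population$N), function(i) {
        copies <- population$haplotypes[(i - 1L) * p + seq_len(p)]
        paste(vapply(copies, function(h) as.integer(id %in% h), integer(1)),
              collapse = "/")
      }, character(1))
      writeLines(paste(c("chr1", format(reg$pos[id] + 1, scientific = FALSE),
                         sprintf("mut%d", id), "A", "T", ".", ".",
                         sprintf("S=%g", reg$s[id]), "GT", gts),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}
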