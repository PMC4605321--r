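# File formats and the top-level pipeline driver. Tabular I/O is TSV with a
# header row and '#' comments; site annotations are accepted as BED (0-based
# half-open) and converted to 1-based inclusive coordinates internally.

#' Load sequence records from FASTA or TSV
#'
#' FASTA records are read with Biostrings; a TSV needs columns `id` and
#' `seq`. Each sequence is validated against its molecule alphabet and T/U
#' normalized (with a warning when conversion was needed).
#'
#' @param path file path (`.fa`/`.fasta` or `.tsv`).
#' @param type `"DNA"` or `"RNA"`.
#' @return data frame with columns `id`, `seq`.
#' @export
load_sequences <- function(path, type = c("DNA", "RNA")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE)) {
    set <- Biostrings::readBStringSet(path)
    ids <- sub("[[:space:]].*$", "", names(set))
    seqs <- as.character(set)
  } else {
    df <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE)
    if (!all(c("id", "seq") %in% names(df))) {
      stop("sequence TSV needs columns 'id' and 'seq'")
    }
    ids <- df$id; seqs <- df$seq
  }
  seqs <- vapply(seq_along(seqs), function(i) {
    tryCatch(normalize_seq(seqs[i], type, warn_converted = TRUE),
             error = function(e) stop(sprintf("record %d ('%s'): %s", i,
                                              ids[i], conditionMessage(e)),
                                      call. = FALSE))
  }, character(1L))
  data.frame(id = ids, seq = unname(seqs), stringsAsFactors = FALSE)
}

#' Read site annotations from BED
#'
#' BED intervals (0-based, half-open) are converted to 1-based inclusive bp
#' coordinates.
#'
#' @param path BED file (chrom, start, end, name).
#' @return data frame with `name`, `start`, `end`, `center` (1-based
#'   inclusive).
#' @export
read_sites_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED file needs at least 3 columns")
  names(df)[1:3] <- c("chrom", "start", "end")
  nm <- if (ncol(df) >= 4L) df[[4L]] else paste0("site_", seq_len(nrow(df)))
  start1 <- df$start + 1L
  data.frame(name = nm, start = start1, end = df$end,
             center = (start1 + df$end) / 2, stringsAsFactors = FALSE)
}

#' Write a trajectory ensemble as TSV
#'
#' Columns `replicate`, `time`, `m` (the state entered at `time`).
#'
#' @param trajs an `rloop_ensemble` or list of trajectories.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_trajectories_tsv <- function(trajs, path) {
  trajs <- .as_ensemble(trajs)
  df <- do.call(rbind, lapply(seq_along(trajs), function(i) {
    data.frame(replicate = i, time = trajs[[i]]$times,
               m = trajs[[i]]$states)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rloopkmc trajectories: reps=%d max_t=%g m0=%d N=%d boundary=%s",
                     length(trajs), trajs[[1L]]$max_t, trajs[[1L]]$m0,
                     trajs[[1L]]$N, trajs[[1L]]$boundary), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory ensemble TSV
#'
#' @param path TSV written by [write_trajectories_tsv()].
#' @return an `rloop_ensemble`.
#' @export
read_trajectories_tsv <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- as.list(stats::setNames(
    sub("^.*=", "", strsplit(sub("^#[^:]*: *", "", hdr), " ")[[1L]]),
    sub("=.*$", "", strsplit(sub("^#[^:]*: *", "", hdr), " ")[[1L]])))
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  out <- lapply(split(df, df$replicate), function(d) {
    structure(list(times = d$time, states = as.integer(d$m),
                   m0 = as.integer(meta$m0), max_t = as.numeric(meta$max_t),
                   N = as.integer(meta$N),
                   absorbed = d$m[nrow(d)] == 0L &&
                     identical(meta$boundary, "absorbing"),
                   t_abs = NA_real_, boundary = meta$boundary),
              class = "rloop_trajectory")
  })
  out <- out[order(as.integer(names(out)))]
  names(out) <- NULL
  class(out) <- "rloop_ensemble"
  out
}

#' Run the specificity pipeline end to end
#'
#' Reads (or accepts) a pair table, runs filtering, per-record KMC stability
#' metrics and the permutation correlation, and writes record-level metrics,
#' a summary JSON and a provenance record to `out_dir`.
#'
#' @param config list (or path to a YAML file) with elements `pairs` (TSV
#'   path or data frame), `out_dir`, and optional overrides `m_star`, `reps`,
#'   `m0`, `max_t`, `k0`, `n_perm`, `seed`, `distal_cutoff`, `method`,
#'   `energy_table` (JSON path), `mismatch_table` (JSON path).
#' @return the `specificity_fit`, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(m_star = 16, reps = 1000, m0 = 10, max_t = 100, k0 = 1,
                   n_perm = 100000, seed = 1, distal_cutoff = 10,
                   method = "pearson")
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$pairs)) stop("config stage: 'pairs' is required")
  if (is.null(cfg$out_dir)) stop("config stage: 'out_dir' is required")
  model <- if (!is.null(cfg$energy_table)) {
    if (!file.exists(cfg$energy_table)) {
      stop("config stage: energy table not found: ", cfg$energy_table)
    }
    read_energy_model(cfg$energy_table, cfg$mismatch_table)
  } else default_energy_model()
  records <- if (is.data.frame(cfg$pairs)) cfg$pairs else
    read_pairs_tsv(cfg$pairs)
  t0 <- proc.time()[["elapsed"]]
  fit <- specificity_analysis(records, model, m_star = cfg$m_star,
                              reps = cfg$reps, m0 = cfg$m0,
                              max_t = cfg$max_t, k0 = cfg$k0,
                              n_perm = cfg$n_perm, seed = cfg$seed,
                              distal_cutoff = cfg$distal_cutoff,
                              method = cfg$method)
  elapsed <- proc.time()[["elapsed"]] - t0
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(fit$records, file.path(cfg$out_dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(r = fit$correlation$r, p_perm = fit$correlation$p_perm,
                  n = fit$correlation$n, settings = fit$settings)
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  provenance <- list(package = "rloopkmc",
                     version = as.character(utils::packageVersion("rloopkmc")),
                     seed = cfg$seed, elapsed_s = elapsed,
                     config = cfg[setdiff(names(cfg), "pairs")])
  jsonlite::write_json(provenance, file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(fit)
}
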