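# End-to-end orchestration: simulate -> call -> de novo -> hallmarks ->
# sensitivity -> rate -> bias, with input validation and a reproducible run
# manifest.

#' Validate pipeline input files
#'
#' Structural checks for FASTA, BED and TSV inputs: readability, record
#' structure, numeric and ordered coordinates (0-based, half-open). Failures
#' are enumerated with line numbers; an empty report means all inputs are
#' valid.
#'
#' @param files Named character vector mapping format (`"fasta"`, `"bed"`,
#'   `"tsv"`) to path, e.g. `c(bed = "genes.bed")`; repeat names for several
#'   files of one format.
#' @return Tibble: `file`, `line` (`NA` for file-level problems),
#'   `severity` (`"fatal"` or `"error"`), `message`.
#' @export
validate_inputs <- function(files) {
  stopifnot(!is.null(names(files)))
  report <- list()
  add <- function(file, line, severity, message) {
    report[[length(report) + 1L]] <<-
      tibble(file = file, line = line, severity = severity, message = message)
  }
  for (i in seq_along(files)) {
    fmt <- names(files)[i]
    path <- files[[i]]
    if (!file.exists(path)) {
      add(path, NA_integer_, "fatal", "file not found")
      next
    }
    lines <- tryCatch(readLines(path, warn = FALSE),
                      error = function(e) NULL)
    if (is.null(lines)) {
      add(path, NA_integer_, "fatal", "file unreadable")
      next
    }
    if (fmt == "fasta") {
      hdr <- grep("^>", lines)
      if (length(hdr) == 0L) {
        add(path, 1L, "fatal", "no FASTA record header ('>') found")
        next
      }
      if (any(nzchar(trimws(lines[seq_len(hdr[1] - 1L)])))) {
        add(path, 1L, "error", "sequence data before first FASTA header")
      }
      ends <- c(hdr[-1] - 1L, length(lines))
      for (j in seq_along(hdr)) {
        body <- lines[seq(hdr[j] + 1L, length.out = max(0L, ends[j] - hdr[j]))]
        if (!any(nzchar(trimws(body)))) {
          add(path, hdr[j], "fatal", "truncated FASTA record (header without sequence)")
        }
      }
    } else if (fmt == "bed") {
      body <- which(!grepl("^#", lines) & nzchar(lines))
      for (j in body) {
        f <- strsplit(lines[j], "\t", fixed = TRUE)[[1]]
        if (length(f) < 3L) {
          add(path, j, "error", "fewer than 3 BED columns")
          next
        }
        s <- suppressWarnings(as.numeric(f[2]))
        e <- suppressWarnings(as.numeric(f[3]))
        if (is.na(s) || is.na(e)) {
          add(path, j, "error", "non-numeric start/end")
        } else if (s > e) {
          add(path, j, "error", "start > end")
        } else if (s < 0) {
          add(path, j, "error", "negative start")
        }
      }
    } else if (fmt == "tsv") {
      body <- which(!grepl("^#", lines) & nzchar(lines))
      if (length(body) == 0L) {
        add(path, NA_integer_, "error", "no records")
      } else {
        ncol0 <- length(strsplit(lines[body[1]], "\t", fixed = TRUE)[[1]])
        for (j in body[-1]) {
          n <- length(strsplit(lines[j], "\t", fixed = TRUE)[[1]])
          if (n != ncol0) add(path, j, "error",
                             sprintf("expected %d fields, found %d", ncol0, n))
        }
      }
    } else {
      add(path, NA_integer_, "fatal", sprintf("unknown format '%s'", fmt))
    }
  }
  if (length(report) == 0L) {
    tibble(file = character(), line = integer(), severity = character(),
           message = character())
  } else {
    bind_rows(report)
  }
}

#' Default pipeline configuration
#'
#' The bundled demo configuration: a 1-Mb two-chromosome genome, the default
#' family mix, and every reporting constant at its standard value (2 unique
#' amplicons, 5 nt separation, 10 subsampling replicates, 5% VAF floor,
#' one million permutations).
#'
#' @param seed Master seed.
#' @param n_perm Permutation count for the positional-bias stage.
#' @return Configuration list accepted by [run_pipeline()].
#' @export
pipeline_config <- function(seed = 1L, n_perm = 1e6) {
  list(seed = seed,
       simulate = list(),
       call = list(window = 200, min_unique = 2, min_sep = 5),
       denovo = list(match_window = 100),
       sensitivity = list(grid_by = 0.01, reps = 10),
       rate = list(vaf_floor = 0.05),
       bias = list(n_perm = n_perm))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order on a simulated library, writing
#' every intermediate to `out_dir` and a JSON run manifest with per-stage
#' wall-clock times and output checksums. Identical configurations (and
#' seeds) produce identical checksums.
#'
#' Stages: `simulate` (library on disk), `call` (junction calls),
#' `denovo` (catalog filter; single-sample mode), `hallmarks` (structural
#' annotation of de novo candidates, via the simulator's resolved
#' sequences), `sensitivity` (germline detection curve), `rate`
#' (sensitivity-corrected de novo rate), `bias` (positional-bias permutation
#' test over intragenic insertions).
#'
#' @param config Configuration list from [pipeline_config()] (or a path to
#'   a YAML/JSON file of the same shape).
#' @param out_dir Output directory.
#' @param stages Character vector of stages to run.
#' @return Invisibly, a list with the manifest and key in-memory results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         stages = c("simulate", "call", "denovo", "hallmarks",
                                    "sensitivity", "rate", "bias")) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  config_hash <- substr(rlang::hash(config), 1, 12)
  manifest <- list(tool = "retrotrace",
                   version = as.character(utils::packageVersion("retrotrace")),
                   config = config, config_hash = config_hash, stages = list())
  results <- list()
  t_stage <- function(name, expr) {
    t0 <- Sys.time()
    message(sprintf("[%s] starting", name))
    out <- force(expr)
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    message(sprintf("[%s] done in %.1fs", name, dt))
    manifest$stages[[name]] <<- list(seconds = round(dt, 2))
    out
  }

  sim_args <- config$simulate %||% list()
  sim_args$seed <- seed
  sim_cfg <- do.call(sim_config, sim_args)
  library <- consensus_library()

  if ("simulate" %in% stages) {
    sim <- t_stage("simulate",
                   simulate_library(sim_cfg, file.path(out_dir, "sim")))
    results$sim <- sim
  } else {
    reads_path <- file.path(out_dir, "sim", "reads.tsv")
    if (!file.exists(reads_path)) {
      abort("simulate stage disabled but no reads file present; run validate first")
    }
    results$sim <- list(reads = read_stage_tsv(reads_path),
                        paths = c(reads = reads_path))
  }

  if ("call" %in% stages) {
    cc <- config$call %||% list()
    calls <- t_stage("call", call_junctions(
      results$sim$reads,
      window = cc$window %||% 200, min_unique = cc$min_unique %||% 2,
      min_sep = cc$min_sep %||% 5))
    write_stage_tsv(calls, file.path(out_dir, "calls.tsv"), "call", seed,
                    config_hash)
    write_bed(calls %>%
                mutate(start = .data$junction, end = .data$junction + 1L,
                       name = .data$family, score = .data$n_unique_amplicons,
                       strand = "+") %>%
                select("chrom", "start", "end", "name", "score", "strand"),
              file.path(out_dir, "calls.bed"), "call", seed, config_hash)
    results$calls <- calls
  }

  if ("denovo" %in% stages && !is.null(results$calls)) {
    dn <- config$denovo %||% list()
    denovo <- t_stage("denovo", {
      match_catalog(results$calls, results$sim$catalog %>%
                      rename(family = "name"),
                    match_window = dn$match_window %||% 100)
    })
    write_stage_tsv(denovo, file.path(out_dir, "denovo.tsv"), "denovo", seed,
                    config_hash)
    results$denovo <- denovo
  }

  if ("hallmarks" %in% stages && !is.null(results$denovo)) {
    hm <- t_stage("hallmarks", {
      trips <- insertion_triplets(results$sim$genome,
                                  filter(results$sim$truth, !.data$germline))
      annotate_hallmarks(trips, library = library)
    })
    write_stage_tsv(hm, file.path(out_dir, "hallmarks.tsv"), "hallmarks",
                    seed, config_hash)
    results$hallmarks <- hm
  }

  if ("sensitivity" %in% stages && !is.null(results$calls)) {
    sn <- config$sensitivity %||% list()
    curve <- t_stage("sensitivity", subsample_detection(
      results$sim$reads,
      results$sim$truth %>% filter(.data$germline) %>%
        select("id", "family"),
      grid = seq(sn$grid_by %||% 0.01, 1, by = sn$grid_by %||% 0.01),
      reps = sn$reps %||% 10, seed = seed + 10L))
    write_stage_tsv(tidy(curve), file.path(out_dir, "detection_curve.tsv"),
                    "sensitivity", seed, config_hash)
    results$curve <- curve
  }

  if ("rate" %in% stages && !is.null(results$curve)) {
    rt <- config$rate %||% list()
    rate <- t_stage("rate", {
      denovo_truth <- results$sim$truth %>% filter(!.data$germline)
      curves <- insertion_detection_curves(
        results$sim$reads, select(denovo_truth, "id", "family"),
        seed = seed + 11L)
      estimate_insertion_rate(select(denovo_truth, "id", "vaf"), curves,
                              vaf_floor = rt$vaf_floor %||% 0.05)
    })
    jsonlite::write_json(glance(rate), file.path(out_dir, "rate.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    results$rate <- rate
  }

  if ("bias" %in% stages) {
    bi <- config$bias %||% list()
    bias <- t_stage("bias", {
      genes <- results$sim$genome$genes
      ins <- results$sim$truth %>%
        select(id = "id", chrom = "chrom", pos = "position")
      pct <- gene_percentile(ins, genes, intergenic = "drop")
      if (nrow(pct) == 0L) NULL
      else permutation_test(pct$percentile, genes,
                            n_perm = bi$n_perm %||% 1e6, seed = seed + 12L)
    })
    if (!is.null(bias)) {
      jsonlite::write_json(glance(bias), file.path(out_dir, "bias.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
      results$bias <- bias
    }
  }

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$checksums <- as.list(tools::md5sum(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  results$manifest <- manifest
  invisible(results)
}
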