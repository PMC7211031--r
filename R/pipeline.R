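#' End-to-end hotspot detection on a mutation table
#'
#' Orchestrates the full detection pipeline: restrict to records with a
#' protein position, aggregate distinct patients per (gene, position), fit
#' the per-gene beta-binomial + stepwise fixed effects, assign p-values,
#' BH-correct over warm spots, and apply the final filter.
#'
#' @param records canonical mutation record data.frame (from [read_maf()]
#'   or [simulate_cohort()]).
#' @param n_patients cohort size; `"auto"` counts distinct patients in
#'   `records`.
#' @param per_cancer_type if `TRUE`, run the whole analysis separately per
#'   cancer type; default is a pooled (pan-cohort) run.
#' @param protein_lengths optional named vector gene -> protein length used
#'   to size histogram bin 0; otherwise the max mutated position is used.
#' @param warm_min,q_max,patients_min filtering constants (defaults 4,
#'   0.01, 7).
#' @param kl_stop,frac_grid,max_steps_mult stepwise parameters: stop below
#'   this scaled divergence, the removal fraction grid, and the step cap as
#'   a multiple of the histogram bin count.
#' @param dedup_patients count distinct patients per site (default) or raw
#'   rows.
#' @param min_gene_mutations genes with fewer mutated positions than this
#'   are skipped (a model on 1-2 positions is meaningless).
#' @return list with `hotspots` (one row per mutated position, all genes)
#'   and `models` (per gene and bin: `h`, model expectation, `F`), plus
#'   `params`.
#' @export
detect_hotspots <- function(records, n_patients = "auto",
                            per_cancer_type = FALSE,
                            protein_lengths = NULL,
                            warm_min = 4L, q_max = 0.01, patients_min = 7L,
                            kl_stop = 1, frac_grid = seq(0.1, 1, by = 0.1),
                            max_steps_mult = 3L, dedup_patients = TRUE,
                            min_gene_mutations = 3L) {
  if (per_cancer_type) {
    parts <- lapply(split(records, records$cancer_type), detect_hotspots,
                    n_patients = n_patients, per_cancer_type = FALSE,
                    protein_lengths = protein_lengths, warm_min = warm_min,
                    q_max = q_max, patients_min = patients_min,
                    kl_stop = kl_stop, frac_grid = frac_grid,
                    max_steps_mult = max_steps_mult,
                    dedup_patients = dedup_patients,
                    min_gene_mutations = min_gene_mutations)
    hot <- do.call(rbind, lapply(names(parts), function(ct)
      cbind(cancer_type = ct, parts[[ct]]$hotspots)))
    mod <- do.call(rbind, lapply(names(parts), function(ct)
      cbind(cancer_type = ct, parts[[ct]]$models)))
    return(list(hotspots = hot, models = mod,
                params = parts[[1L]]$params))
  }

  coding <- filter_coding(records)
  if (n_patients == "auto")
    n_patients <- length(unique(records$patient_id))
  n_patients <- as.integer(n_patients)
  params <- list(n_patients = n_patients, warm_min = warm_min, q_max = q_max,
                 patients_min = patients_min, kl_stop = kl_stop,
                 max_steps_mult = max_steps_mult,
                 dedup_patients = dedup_patients)
  empty_calls <- call_hotspots(list(gene = character(0), counts = integer(0)),
                               NULL, numeric(1))
  if (!nrow(coding))
    return(list(hotspots = empty_calls, models = data.frame(), params = params))

  pcs <- aggregate_positions(coding, dedup_patients = dedup_patients,
                             protein_lengths = protein_lengths)
  all_calls <- list()
  all_models <- list()
  for (pc in pcs) {
    if (length(pc$counts) < min_gene_mutations) next
    hist <- build_histogram(pc, n_patients)
    sw <- stepwise_fixed_effects(hist, frac_grid = frac_grid,
                                 kl_stop = kl_stop,
                                 max_steps = max_steps_mult * max(hist$k, 1L))
    calls <- call_hotspots(pc, sw$fit, sw$F)
    all_calls[[pc$gene]] <- calls
    expd <- sum(sw$reduced) *
      .bb_model_pmf(hist$k, n_patients, sw$fit$a, sw$fit$b)
    all_models[[pc$gene]] <- data.frame(
      gene = pc$gene, i = 0:hist$k, h = hist$h, expected = expd, F = sw$F,
      a = sw$fit$a, b = sw$fit$b, kl_scaled = sw$fit$kl_scaled,
      n_steps = sw$n_steps, stringsAsFactors = FALSE
    )
  }
  if (!length(all_calls))
    return(list(hotspots = empty_calls, models = data.frame(), params = params))
  hot <- do.call(rbind, all_calls)
  rownames(hot) <- NULL
  hot <- fdr_correct(hot, warm_min = warm_min)
  hot <- filter_hotspots(hot, q_max = q_max, patients_min = patients_min)
  list(hotspots = hot, models = do.call(rbind, c(all_models,
                                                 make.row.names = FALSE)),
       params = params)
}

#' Annotate a hotspot table with hairpin and dN/dS columns
#'
#' @param hotspots data.frame from [detect_hotspots()] (needs `gene`,
#'   `protein_pos`).
#' @param records the mutation records the hotspots came from (used to find
#'   each hotspot's genomic position and, for dN/dS, the per-gene
#'   consequence tallies).
#' @param reference reference sequence for [extract_context()]; `NULL`
#'   skips hairpin annotation.
#' @param cds named list/vector of coding sequences keyed by gene; `NULL`
#'   skips dN/dS annotation.
#' @param table hairpin threshold table.
#' @param window,max_stem hairpin scan parameters.
#' @return `hotspots` with added columns `ss`, `loop_length`,
#'   `loop_position`, `hairpin_label`, `strand_flipped` and/or `wmis`,
#'   `wnon`, `w_summary`.
#' @export
annotate_hotspots <- function(hotspots, records, reference = NULL, cds = NULL,
                              table = hairpin_thresholds(), window = 25L,
                              max_stem = 10L) {
  out <- hotspots
  if (!is.null(reference)) {
    out$ss <- NA_integer_
    out$loop_length <- NA_integer_
    out$loop_position <- NA_integer_
    out$hairpin_label <- NA_character_
    out$strand_flipped <- NA
    for (j in seq_len(nrow(out))) {
      hit <- records$gene == out$gene[j] &
        !is.na(records$protein_pos) &
        records$protein_pos == out$protein_pos[j]
      if (!any(hit)) next
      rec <- records[which(hit)[1L], ]
      ann <- annotate_mutation(reference, rec, table = table,
                               window = window, max_stem = max_stem)
      out$hairpin_label[j] <- ann$label
      out$strand_flipped[j] <- ann$strand_flipped
      if (!is.null(ann$best)) {
        out$ss[j] <- ann$best$stem_strength
        out$loop_length[j] <- ann$best$loop_length
        out$loop_position[j] <- ann$best$loop_position
      }
    }
  }
  if (!is.null(cds)) {
    out$wmis <- NA_real_; out$wnon <- NA_real_; out$w_summary <- NA_real_
    for (g in unique(out$gene)) {
      if (!g %in% names(cds)) next
      opp <- opportunities_from_cds(cds[[g]])
      est <- estimate_dnds(records[records$gene == g, , drop = FALSE], opp)
      sel <- out$gene == g
      out$wmis[sel] <- est$wmis
      out$wnon[sel] <- est$wnon
      out$w_summary[sel] <- est$w_summary
    }
  }
  out
}

#' Hypergeometric enrichment of hit genes in a reference list
#'
#' Upper-tail probability of observing at least the actual overlap between
#' the hit genes and a reference gene list, drawing `|hits|` genes from a
#' universe of `universe_size`.
#'
#' @param hit_genes character vector (e.g. genes carrying hotspots).
#' @param reference_genes character vector (e.g. a cancer gene census).
#' @param universe_size total number of genes considered.
#' @return list with `overlap`, `p_value`.
#' @export
enrichment_test <- function(hit_genes, reference_genes, universe_size) {
  hit_genes <- unique(hit_genes)
  reference_genes <- unique(reference_genes)
  if (length(hit_genes) > universe_size || length(reference_genes) > universe_size)
    stop("gene sets larger than the universe")
  ov <- length(intersect(hit_genes, reference_genes))
  p <- stats::phyper(ov - 1, length(reference_genes),
                     universe_size - length(reference_genes),
                     length(hit_genes), lower.tail = FALSE)
  list(overlap = ov, p_value = p)
}

# ---- command-line entry points ---------------------------------------------

.tool_header <- function(params) {
  paste0("# hotspotr ", as.character(utils::packageVersion("hotspotr")), " | ",
         paste(names(params), unlist(lapply(params, format)), sep = "=",
               collapse = " "))
}

.write_tsv <- function(df, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(params)) writeLines(.tool_header(params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run hotspot detection from the command line
#'
#' `hotspotr detect --maf FILE --out DIR [--per-cancer-type] [--n-patients N]`
#' Writes `hotspots.tsv` (one row per mutated position with p, q, warm and
#' filter flags) and `models.tsv` (per-gene fit: observed bins, model
#' expectation, fixed effect) into `--out`.
#'
#' @param args character vector of command-line arguments.
#' @return exit status, invisibly (0 ok, 1 user error).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: hotspotr <command> [options]",
    "commands:",
    "  detect   --maf FILE --out DIR [--n-patients N|auto]",
    "           [--per-cancer-type] [--q-max X] [--patients-min N]",
    "           [--warm-min N] [--kl-stop X]",
    "  annotate --hotspots FILE --maf FILE --out FILE [--ref FASTA]",
    "           [--cds FASTA]",
    "  simulate --out DIR [--seed N] [--n-patients N] [--genes N]",
    sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1L]
  opts <- .parse_cli_opts(args[-1L])
  need <- function(k) {
    if (is.null(opts[[k]])) stop("missing required option --", k, call. = FALSE)
    opts[[k]]
  }
  status <- tryCatch({
    switch(cmd,
      detect = {
        records <- read_maf(need("maf"))
        res <- detect_hotspots(
          records,
          n_patients = if (is.null(opts[["n-patients"]])) "auto"
                       else opts[["n-patients"]],
          per_cancer_type = isTRUE(opts[["per-cancer-type"]]),
          warm_min = as.integer(opts[["warm-min"]] %||% 4L),
          q_max = as.numeric(opts[["q-max"]] %||% 0.01),
          patients_min = as.integer(opts[["patients-min"]] %||% 7L),
          kl_stop = as.numeric(opts[["kl-stop"]] %||% 1))
        dir.create(need("out"), showWarnings = FALSE, recursive = TRUE)
        .write_tsv(res$hotspots, file.path(opts[["out"]], "hotspots.tsv"),
                   res$params)
        .write_tsv(res$models, file.path(opts[["out"]], "models.tsv"),
                   res$params)
        message("detect: ", sum(res$hotspots$passes_filter, na.rm = TRUE),
                " hotspot(s) pass the filter, ",
                sum(res$hotspots$is_warm, na.rm = TRUE), " warm spot(s)")
        0L
      },
      annotate = {
        hot <- utils::read.delim(need("hotspots"), comment.char = "#",
                                 stringsAsFactors = FALSE)
        records <- read_maf(need("maf"))
        cds <- NULL
        if (!is.null(opts[["cds"]])) {
          ss <- Biostrings::readDNAStringSet(opts[["cds"]])
          cds <- stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
        }
        ann <- annotate_hotspots(hot, records, reference = opts[["ref"]],
                                 cds = cds)
        .write_tsv(ann, need("out"), list(command = "annotate"))
        0L
      },
      simulate = {
        seed <- as.integer(opts[["seed"]] %||% 1L)
        np <- as.integer(opts[["n-patients"]] %||% 200L)
        ng <- as.integer(opts[["genes"]] %||% 5L)
        genes <- data.frame(name = sprintf("G%02d", seq_len(ng)),
                            protein_length = 500L, a = 0.05, b = 400)
        spec <- sim_spec(np, genes, seed = seed)
        sim <- simulate_cohort(spec)
        dir.create(need("out"), showWarnings = FALSE, recursive = TRUE)
        write_maf(sim$records, file.path(opts[["out"]], "simulated.maf"))
        .write_tsv(sim$truth, file.path(opts[["out"]], "truth.tsv"),
                   list(seed = seed))
        0L
      },
      { message("unknown command: ", cmd, "\n", usage); 1L }
    )
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    key <- substring(a, 3L)
    if (i < length(args) && !startsWith(args[i + 1L], "--")) {
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      opts[[key]] <- TRUE
      i <- i + 1L
    }
  }
  opts
}
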