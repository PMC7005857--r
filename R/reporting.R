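# Summary tables: per-section and per-gene-pool counts of evaluated,
# qualifying, screened, tolerant, reviewed and resistant taxa, with
# percentages at three aggregation levels (taxon, section, gene pool). A
# section or gene pool qualifies for a criterion iff at least one member
# taxon qualifies. Percentages are rounded half-up to integers.

#' Round half-up to integer percent
#'
#' @param x numeric.
#' @return integer-valued numeric (e.g. 11.69 -> 12, 2.5 -> 3).
#' @export
round_half_up <- function(x) floor(x + 0.5)

CLIMATE_COLS <- c("AMEANT", "TWETQ", "AP", "PWETQ")
ASSAY_COLS <- c("dehydration", "salinity")

#' Count evaluated and qualifying taxa per section and gene pool
#'
#' One row per section plus a total row per gene pool: number of taxa
#' evaluated in the ecogeographic analysis (non-nd climate columns),
#' qualifying per climate criterion (level `high`, i.e. HSD group 1),
#' screened and tolerant (high) per assay, and reviewed / resistant per
#' stressor in the resistance table.
#'
#' @param tolerance_matrix output of [merge_screening()].
#' @param resistance resistance data.frame (or NULL).
#' @param taxonomy taxonomy data.frame.
#' @return data.frame of counts (`level` is "section" or "gene_pool").
#' @export
summarize_counts <- function(tolerance_matrix, resistance, taxonomy) {
  miss <- setdiff(tolerance_matrix$taxon_id, taxonomy$taxon_id)
  if (length(miss)) stop("taxa missing from taxonomy: ",
                         paste(miss, collapse = ", "))
  tm <- merge(tolerance_matrix, taxonomy[c("taxon_id", "section", "gene_pool")],
              by = "taxon_id")
  stressors <- if (!is.null(resistance)) sort(unique(resistance$stressor)) else character(0)
  tally <- function(d) {
    evaluated <- d$taxon_id[apply(d[CLIMATE_COLS] != "nd", 1, any)]
    row <- data.frame(n_taxa = nrow(d), n_evaluated = length(evaluated))
    for (cc in CLIMATE_COLS) row[[paste0("q_", cc)]] <- sum(d[[cc]] == "high")
    row$n_screened <- sum(apply(d[ASSAY_COLS] != "nd", 1, any))
    for (a in ASSAY_COLS) row[[paste0("tol_", a)]] <- sum(d[[a]] == "high")
    for (s in stressors) {
      r <- resistance[resistance$stressor == s &
                        resistance$taxon_id %in% d$taxon_id, ]
      row[[paste0("rev_", s)]] <- sum(r$status != "not_evaluated")
      row[[paste0("res_", s)]] <- sum(r$status == "resistant_reported")
    }
    row
  }
  rows <- list()
  for (gp in sort(unique(tm$gene_pool))) {
    dgp <- tm[tm$gene_pool == gp, ]
    for (sec in sort(unique(dgp$section))) {
      rows[[length(rows) + 1]] <- cbind(
        data.frame(level = "section", gene_pool = gp, unit = sec,
                   stringsAsFactors = FALSE),
        tally(dgp[dgp$section == sec, ]))
    }
    rows[[length(rows) + 1]] <- cbind(
      data.frame(level = "gene_pool", gene_pool = gp, unit = gp,
                 stringsAsFactors = FALSE),
      tally(dgp))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percentages of qualifying units at taxon, section and gene-pool level
#'
#' A unit (taxon, section or gene pool) qualifies for a criterion iff at
#' least one member taxon qualifies; denominators are the units evaluated
#' (respectively screened, reviewed) for that criterion family. Percentages
#' use half-up integer rounding. Rows with zero denominator are suppressed
#' with a warning.
#'
#' @param tolerance_matrix output of [merge_screening()].
#' @param resistance resistance data.frame (or NULL).
#' @param taxonomy taxonomy data.frame.
#' @return data.frame: `criterion`, `level`, `n_evaluated`, `n_qualifying`,
#'   `pct`.
#' @export
summarize_percentages <- function(tolerance_matrix, resistance, taxonomy) {
  tm <- merge(tolerance_matrix, taxonomy[c("taxon_id", "section", "gene_pool")],
              by = "taxon_id")
  units <- list(taxon = tm$taxon_id, section = tm$section,
                gene_pool = tm$gene_pool)
  rows <- list()
  emit <- function(criterion, level, eval_units, qual_units) {
    n_eval <- length(unique(eval_units))
    n_qual <- length(unique(qual_units))
    if (n_eval == 0) {
      warning("no evaluated units for ", criterion, " at level ", level)
      return()
    }
    rows[[length(rows) + 1]] <<- data.frame(
      criterion = criterion, level = level, n_evaluated = n_eval,
      n_qualifying = n_qual, pct = round_half_up(100 * n_qual / n_eval),
      stringsAsFactors = FALSE)
  }
  eval_clim <- apply(tm[CLIMATE_COLS] != "nd", 1, any)
  for (cc in CLIMATE_COLS) {
    for (lv in names(units)) {
      emit(cc, lv, units[[lv]][eval_clim],
           units[[lv]][eval_clim & tm[[cc]] == "high"])
    }
  }
  scr <- apply(tm[ASSAY_COLS] != "nd", 1, any)
  for (a in ASSAY_COLS) {
    for (lv in names(units)) {
      emit(a, lv, units[[lv]][scr], units[[lv]][scr & tm[[a]] == "high"])
    }
  }
  if (!is.null(resistance) && nrow(resistance)) {
    res <- merge(resistance, taxonomy[c("taxon_id", "section", "gene_pool")],
                 by = "taxon_id")
    runits <- list(taxon = res$taxon_id, section = res$section,
                   gene_pool = res$gene_pool)
    for (s in sort(unique(res$stressor))) {
      d <- res$stressor == s
      ev <- d & res$status != "not_evaluated"
      rs <- d & res$status == "resistant_reported"
      for (lv in names(runits)) emit(s, lv, runits[[lv]][ev], runits[[lv]][rs])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-stressor resistance percentages
#'
#' Evaluated = taxa with status other than `not_evaluated`; the percentage of
#' those with reported resistance (half-up rounding).
#'
#' @param resistance resistance data.frame.
#' @return data.frame: `stressor`, `n_evaluated`, `n_resistant`, `pct`.
#' @export
resistance_summary <- function(resistance) {
  out <- do.call(rbind, lapply(split(resistance, resistance$stressor), function(d) {
    n_eval <- sum(d$status != "not_evaluated")
    n_res <- sum(d$status == "resistant_reported")
    data.frame(stressor = d$stressor[1], n_evaluated = n_eval,
               n_resistant = n_res,
               pct = if (n_eval > 0) round_half_up(100 * n_res / n_eval) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Executes clean -> extract -> classify -> (optionally) model -> gaps ->
#' report on a simulated or loaded input bundle, writing CSV artifacts and a
#' machine-readable run log when `out_dir` is given. Deterministic given the
#' config.
#'
#' @param world input bundle as produced by [simulate_world()] (or assembled
#'   from the readers: `records`, `countries`, `stack`, `taxonomy`,
#'   `accessions`, `screening`, `resistance`).
#' @param config list: cleaning parameters (see [clean_pipeline()]), `alpha`,
#'   `min_records`, `model_taxa` (taxon ids to model; NULL = none, "all" =
#'   every taxon), niche-protocol settings (see [run_protocol()]), `seed`.
#' @param out_dir optional output directory for CSV artifacts.
#' @return list with `cleaned`, `report`, `hsd`, `tolerance`, `status`,
#'   `richness` (sampled/unconserved and, when modelled, gap rasters),
#'   `priorities`, `counts`, `percentages`, `resistance_summary`, `log`.
#' @export
run_pipeline <- function(world, config = list(), out_dir = NULL) {
  cfg <- utils::modifyList(list(alpha = 0.05, min_records = 5,
                                model_taxa = NULL, seed = 1L), config)
  t0 <- Sys.time()
  cl <- clean_pipeline(world$records, world$countries, world$stack, cfg)
  hsd <- classify_all(cl$records, world$stack, cfg$alpha, cfg$min_records)
  tol <- merge_screening(hsd, world$screening,
                         taxa = world$taxonomy$taxon_id)
  status <- exsitu_status(world$accessions, world$taxonomy)
  g <- world$stack$grid
  rich_all <- sampled_richness(cl$records, g)
  rich_herb <- sampled_richness(cl$records, g, source_filter = "herbarium")
  rich_gene <- sampled_richness(cl$records, g,
                                source_filter = c("genebank", "living_collection"))
  rich_uncon <- unconserved_richness(cl$records, status, g)

  model_taxa <- cfg$model_taxa
  if (identical(model_taxa, "all")) model_taxa <- unique(cl$records$taxon_id)
  maps <- list(); gap <- NULL; priorities <- NULL
  if (length(model_taxa)) {
    for (tx in model_taxa) {
      pts <- as.matrix(cl$records[cl$records$taxon_id == tx, c("lon", "lat")])
      sm <- run_protocol(pts, world$stack,
                         utils::modifyList(cfg, list(seed = sub_seed(cfg$seed,
                                                                     match(tx, model_taxa)))))
      if (!isTRUE(sm$skipped)) maps[[tx]] <- sm$binary
    }
    if (length(maps)) {
      gap <- modelled_gap(maps, cl$records, g)
      priorities <- priority_countries(gap, world$countries)
    }
  }
  counts <- summarize_counts(tol, world$resistance, world$taxonomy)
  pct <- summarize_percentages(tol, world$resistance, world$taxonomy)
  res_sum <- resistance_summary(world$resistance)
  log <- list(seed = cfg$seed, alpha = cfg$alpha,
              n_records_in = nrow(world$records),
              n_records_clean = nrow(cl$records),
              steps = cl$report$steps,
              n_taxa = nrow(world$taxonomy),
              n_modelled = length(maps),
              elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  out <- list(cleaned = cl$records, report = cl$report, hsd = hsd,
              tolerance = tol, status = status,
              richness = list(all = rich_all, herbarium = rich_herb,
                              genebank = rich_gene, unconserved = rich_uncon,
                              gap = gap),
              maps = maps, priorities = priorities, counts = counts,
              percentages = pct, resistance_summary = res_sum, log = log)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    wr <- function(x, f) utils::write.csv(x, file.path(out_dir, f), row.names = FALSE)
    write_presence_table(cl$records, file.path(out_dir, "records_clean.csv"))
    wr(cl$report$steps, "cleaning_steps.csv")
    wr(cl$report$detail, "cleaning_detail.csv")
    wr(tol, "tolerance_matrix.csv")
    wr(status, "exsitu_status.csv")
    wr(counts, "summary_counts.csv")
    wr(pct, "summary_percentages.csv")
    wr(res_sum, "resistance_summary.csv")
    if (!is.null(priorities)) wr(priorities, "priority_countries.csv")
    for (nm in names(out$richness)) {
      if (!is.null(out$richness[[nm]])) {
        write_ascii_grid(out$richness[[nm]],
                         file.path(out_dir, paste0("richness_", nm, ".asc")))
      }
    }
    log_out <- log
    log_out$steps <- NULL
    log_out$elapsed_s <- NULL  # timings would break byte-level reproducibility
    jsonlite::write_json(log_out, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA)
    wr(cl$report$steps, "run_log_steps.csv")
  }
  out
}
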