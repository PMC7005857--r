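# Climate-value extraction at record locations, greedy collinearity pruning
# at |r| <= 0.7, and the per-taxon climate summaries behind the four
# harshness columns (annual mean temperature, wettest-quarter temperature,
# annual precipitation, wettest-quarter precipitation).

#' Field names of the four harshness indicator variables
#'
#' AMEANT = BIO1 (annual mean temperature), TWETQ = BIO8 (mean temperature of
#' the wettest quarter), AP = BIO12 (annual precipitation), PWETQ = BIO16
#' (precipitation of the wettest quarter).
#' @export
HARSHNESS_VARS <- c(AMEANT = "BIO1", TWETQ = "BIO8", AP = "BIO12",
                    PWETQ = "BIO16")

#' Extract bioclim values at record locations
#'
#' Each record's row holds the 19 values of the raster cell containing its
#' point (half-open cell convention). Records on nodata cells or outside the
#' raster extent are excluded and reported.
#'
#' @param records `presence_records`.
#' @param stack a `climate_stack`.
#' @return list with `matrix` (data.frame: `record_id`, `taxon_id`, BIO1..19)
#'   and `excluded` (record ids with reasons).
#' @export
extract_values <- function(records, stack) {
  env <- stack_lookup(stack, records$lon, records$lat)
  ix <- cell_index(stack$grid, records$lon, records$lat)
  outside <- is.na(ix$cell)
  nodata <- !outside & !stats::complete.cases(env)
  ok <- !outside & !nodata
  mat <- cbind(data.frame(record_id = records$record_id[ok],
                          taxon_id = records$taxon_id[ok],
                          stringsAsFactors = FALSE),
               as.data.frame(env[ok, , drop = FALSE]))
  excluded <- data.frame(
    record_id = records$record_id[!ok],
    reason = ifelse(outside[!ok], "outside raster extent", "no climate data"),
    stringsAsFactors = FALSE)
  list(matrix = mat, excluded = excluded)
}

#' Greedy pruning of correlated variables
#'
#' Variables are visited in `preferred_order`; one is retained iff its
#' absolute Pearson correlation with every already-retained variable is at
#' most `r_max`. The returned set therefore has all pairwise |r| <= r_max,
#' and every dropped variable violates the bound against some retained one
#' (maximality). Constant columns have undefined correlation and are dropped
#' with a warning.
#'
#' @param env numeric matrix or data.frame of candidate variables.
#' @param r_max correlation threshold (default 0.7).
#' @param preferred_order variable names in retention priority order
#'   (default: column order, i.e. BIO1..BIO19 for a full extraction).
#' @return character vector of retained variable names.
#' @export
prune_correlated <- function(env, r_max = 0.7, preferred_order = NULL) {
  stopifnot(r_max > 0, r_max < 1)
  env <- as.data.frame(env)
  num <- vapply(env, is.numeric, logical(1))
  env <- env[num]
  if (nrow(env) < 2) stop("need >= 2 rows to compute correlations")
  if (is.null(preferred_order)) preferred_order <- names(env)
  const <- vapply(env, function(x) stats::sd(x, na.rm = TRUE) == 0, logical(1))
  if (any(const)) {
    warning("dropping constant column(s): ",
            paste(names(env)[const], collapse = ", "))
  }
  retained <- character()
  for (v in preferred_order) {
    if (!v %in% names(env) || const[[v]]) next
    ok <- all(vapply(retained, function(u) {
      abs(stats::cor(env[[v]], env[[u]], use = "complete.obs")) <= r_max
    }, logical(1)))
    if (ok) retained <- c(retained, v)
  }
  retained
}

#' Per-taxon climate summary
#'
#' Arithmetic means of BIO1, BIO8, BIO12 and BIO16 over each taxon's records
#' (the four harshness indicators). Taxa with no record on a data cell are
#' omitted and reported.
#'
#' @param records `presence_records`.
#' @param stack a `climate_stack`.
#' @return list with `summary` (data.frame: `taxon_id`, `AMEANT`, `TWETQ`,
#'   `AP`, `PWETQ`, `n_records`) and `omitted` (taxon ids).
#' @export
taxon_climate_summary <- function(records, stack) {
  ex <- extract_values(records, stack)
  m <- ex$matrix
  all_taxa <- unique(records$taxon_id)
  if (nrow(m) == 0) {
    return(list(summary = data.frame(), omitted = all_taxa))
  }
  agg <- do.call(rbind, lapply(split(m, m$taxon_id), function(d) {
    data.frame(taxon_id = d$taxon_id[1],
               AMEANT = mean(d$BIO1), TWETQ = mean(d$BIO8),
               AP = mean(d$BIO12), PWETQ = mean(d$BIO16),
               n_records = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  list(summary = agg, omitted = setdiff(all_taxa, agg$taxon_id))
}
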