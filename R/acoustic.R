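#' Read an acoustic detection table
#'
#' Tolerant CSV reader for BirdNET-Analyzer-style outputs. Recognised column
#' dialects (case-insensitive): start seconds (`start_s`, `Start (s)`,
#' `Begin Time (s)`), end seconds (`end_s`, `End (s)`, `End Time (s)`),
#' species (`species`, `Scientific name`, `Common name`), confidence
#' (`confidence`), site (`site_id`, `site`); a missing site column can be
#' supplied via `site_id`.
#'
#' @param path CSV path or a data frame already in some dialect.
#' @param site_id optional site label used when the file has no site column.
#' @return data frame `site_id`, `start_s`, `end_s`, `species`,
#'   `confidence`.
#' @export
read_detections <- function(path, site_id = NULL) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  nm <- tolower(trimws(names(df)))
  pick <- function(cands) {
    hit <- match(tolower(cands), nm)
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0) NA_integer_ else hit[1]
  }
  i_start <- pick(c("start_s", "start (s)", "begin time (s)", "start"))
  i_end   <- pick(c("end_s", "end (s)", "end time (s)", "end"))
  i_sp    <- pick(c("species", "scientific name", "common name"))
  i_conf  <- pick(c("confidence", "conf"))
  i_site  <- pick(c("site_id", "site"))
  if (is.na(i_start) || is.na(i_sp) || is.na(i_conf))
    stop("detection table must provide start time, species and confidence ",
         "columns; found: ", paste(names(df), collapse = ", "))
  out <- data.frame(
    site_id = if (!is.na(i_site)) as.character(df[[i_site]]) else
      if (!is.null(site_id)) rep(as.character(site_id), nrow(df)) else
        stop("no site column found and no `site_id` supplied"),
    start_s = as.numeric(df[[i_start]]),
    end_s = if (!is.na(i_end)) as.numeric(df[[i_end]]) else
      as.numeric(df[[i_start]]) + 3,
    species = as.character(df[[i_sp]]),
    confidence = as.numeric(df[[i_conf]]),
    stringsAsFactors = FALSE)
  validate_detections(out)
  out
}

validate_detections <- function(dets) {
  need <- c("site_id", "start_s", "end_s", "species", "confidence")
  if (!all(need %in% names(dets)))
    stop("detection table must have columns: ", paste(need, collapse = ", "))
  if (nrow(dets) == 0) return(invisible(TRUE))
  bad <- which(!(dets$end_s > dets$start_s) | dets$start_s < 0 |
                 is.na(dets$start_s))
  if (length(bad))
    stop("invalid detection rows (need 0 <= start_s < end_s): rows ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (any(dets$confidence < 0 | dets$confidence > 1, na.rm = TRUE))
    stop("confidence values must lie in [0, 1]")
  invisible(TRUE)
}

#' Screen detections by classifier confidence
#'
#' Keeps rows with confidence greater than or equal to the threshold
#' (inclusive); the number of removed rows is reported as a message.
#'
#' @param dets detection table.
#' @param min_conf minimum confidence (default 0.8).
#' @return the filtered detection table.
#' @export
filter_confidence <- function(dets, min_conf = 0.8) {
  validate_detections(dets)
  keep <- dets$confidence >= min_conf
  if (any(!keep))
    message("filter_confidence: removed ", sum(!keep), " of ", nrow(dets),
            " detections below ", min_conf)
  out <- dets[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove per-site singleton detections
#'
#' A species detected exactly once at a site is likely incidental there; all
#' such species-site pairs are removed. Pairs with two or more detections are
#' kept even when the same species is a singleton at another site.
#'
#' @param dets detection table.
#' @return the filtered detection table.
#' @export
remove_singletons <- function(dets) {
  validate_detections(dets)
  if (nrow(dets) == 0) return(dets)
  key <- paste(dets$site_id, dets$species, sep = "\r")
  n <- table(key)
  out <- dets[n[key] >= 2, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag rare species for manual review and apply removals
#'
#' Species with `max_total` or fewer detections overall are flagged for
#' manual identity checking (the checking itself happens outside the
#' software). The rows of species listed in `removals` — which must all be
#' flagged — are deleted.
#'
#' @param dets detection table.
#' @param max_total flag species with this many detections or fewer
#'   (default 10).
#' @param removals character vector of flagged species whose detections are
#'   incorrect identifications.
#' @return list with `flagged` (data frame `species`, `n_detections`) and
#'   `detections` (the table with removals applied).
#' @export
rare_species_review <- function(dets, max_total = 10, removals = character()) {
  validate_detections(dets)
  counts <- table(dets$species)
  flagged <- names(counts)[counts <= max_total]
  bad <- setdiff(removals, flagged)
  if (length(bad))
    stop("cannot remove species not flagged for review: ",
         paste(bad, collapse = ", "))
  out <- dets[!(dets$species %in% removals), , drop = FALSE]
  rownames(out) <- NULL
  list(flagged = data.frame(species = flagged,
                            n_detections = as.integer(counts[flagged]),
                            row.names = NULL, stringsAsFactors = FALSE),
       detections = out)
}

#' Vocal activity rate per species and site
#'
#' VAR = (number of distinct 15-minute periods in which the species was
#' detected at least once) / (days recorded). Periods are consecutive
#' `period_s`-second bins anchored at each site's recording start; a
#' detection occupies the bin containing its start time; multiple detections
#' within one bin count once.
#'
#' @param dets detection table (already filtered as desired).
#' @param effort data frame `site_id`, `days_recorded` (fractional days,
#'   > 0).
#' @param period_s period length in seconds (default 900 = 15 min).
#' @return data frame `site_id`, `species`, `n_periods`, `var`.
#' @export
var_per_species <- function(dets, effort, period_s = 900) {
  validate_detections(dets)
  stopifnot(all(c("site_id", "days_recorded") %in% names(effort)),
            all(effort$days_recorded > 0))
  if (nrow(dets) == 0)
    return(data.frame(site_id = character(), species = character(),
                      n_periods = integer(), var = numeric(),
                      stringsAsFactors = FALSE))
  m <- match(dets$site_id, effort$site_id)
  if (anyNA(m))
    stop("detections reference sites missing from the effort table: ",
         paste(unique(dets$site_id[is.na(m)]), collapse = ", "))
  span <- effort$days_recorded[m] * 86400
  out_of_span <- which(dets$start_s >= span)
  if (length(out_of_span))
    stop("detections outside the recording span at rows ",
         paste(utils::head(out_of_span, 5), collapse = ", "))
  bin <- floor(dets$start_s / period_s)
  key <- paste(dets$site_id, dets$species, sep = "\r")
  np <- tapply(bin, key, function(b) length(unique(b)))
  parts <- strsplit(names(np), "\r", fixed = TRUE)
  vt <- data.frame(
    site_id = vapply(parts, `[`, "", 1),
    species = vapply(parts, `[`, "", 2),
    n_periods = as.integer(np), row.names = NULL, stringsAsFactors = FALSE)
  vt$var <- vt$n_periods /
    effort$days_recorded[match(vt$site_id, effort$site_id)]
  vt <- vt[order(vt$site_id, vt$species), , drop = FALSE]
  rownames(vt) <- NULL
  vt
}

#' Site-level diversity metrics from a VAR table
#'
#' Richness is the number of species with positive VAR; total VAR is their
#' sum; Shannon diversity is the entropy of VAR shares, `-sum(p log p)` with
#' `p = var / sum(var)` (natural log). Sites listed in `site_ids` but absent
#' from the table get richness 0, VAR 0 and — Shannon being undefined for an
#' empty community — Shannon 0 with a warning.
#'
#' @param vt VAR table from [var_per_species()].
#' @param site_ids optional character vector of all sites that should appear
#'   in the output (defaults to the sites present in `vt`).
#' @return data frame `site_id`, `richness`, `var_total`, `shannon`.
#' @export
site_diversity <- function(vt, site_ids = NULL) {
  stopifnot(all(c("site_id", "species", "var") %in% names(vt)))
  vt <- vt[vt$var > 0, , drop = FALSE]
  ids <- if (is.null(site_ids)) sort(unique(vt$site_id)) else
    as.character(site_ids)
  out <- data.frame(site_id = ids, richness = 0L, var_total = 0,
                    shannon = 0, stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    v <- vt$var[vt$site_id == ids[i]]
    out$richness[i] <- length(v)
    out$var_total[i] <- sum(v)
    if (length(v) > 1) {
      p <- v / sum(v)
      out$shannon[i] <- -sum(p * log(p))
    }
  }
  empty <- out$richness == 0
  if (any(empty))
    warning(sum(empty), " sites have no species; their Shannon diversity is ",
            "undefined and reported as 0")
  out
}

#' Site-by-species community matrix of VAR values
#'
#' @param vt VAR table from [var_per_species()].
#' @return numeric matrix, sites in rows (dimnames set), species in columns.
#' @export
community_matrix <- function(vt) {
  stopifnot(all(c("site_id", "species", "var") %in% names(vt)))
  tab <- stats::xtabs(var ~ site_id + species, data = vt)
  m <- matrix(as.numeric(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  names(dimnames(m)) <- NULL
  m
}

#' Run the standard detection post-processing chain
#'
#' Fixed filtering order: confidence screen, then per-site singleton
#' removal, then the rare-species review, then VAR computation. The order
#' matters: the confidence screen can turn a pair into a singleton, and
#' singleton removal changes the totals the rare review sees.
#'
#' @param dets raw detection table.
#' @param effort data frame `site_id`, `days_recorded`.
#' @param min_conf confidence threshold.
#' @param rare_max_total rare-review flag threshold.
#' @param removals species removed after manual review.
#' @param period_s VAR period length (s).
#' @return list with `var_table`, `flagged`, `detections` (the fully
#'   filtered table).
#' @export
acoustic_pipeline <- function(dets, effort, min_conf = 0.8,
                              rare_max_total = 10, removals = character(),
                              period_s = 900) {
  d <- filter_confidence(dets, min_conf)
  d <- remove_singletons(d)
  rr <- rare_species_review(d, rare_max_total, removals)
  vt <- var_per_species(rr$detections, effort, period_s)
  list(var_table = vt, flagged = rr$flagged, detections = rr$detections)
}
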