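# Per-hemisphere count tables, the study's quality-control gates, the
# region-inclusion filter, and the three connectivity metrics (PPS, FPR,
# starter distribution). The experimental unit throughout is one injected
# hemisphere; region 0 is the "unassigned" pseudo-region (cells mapping
# outside the atlas masks).

UNASSIGNED_ID <- 0L

#' Construct one hemisphere sample
#'
#' @param sample_id unique sample identifier.
#' @param sex `"male"` or `"female"`.
#' @param target injected target, `"amygdala"` or `"ORB"`.
#' @param side `"left"` or `"right"`.
#' @param starters,presynaptic named non-negative integer vectors
#'   (names = region ids; id 0 allowed for unassigned cells).
#' @return a `hemisphere_sample`.
#' @export
hemisphere_sample <- function(sample_id, sex, target, side,
                              starters, presynaptic) {
  stopifnot(sex %in% c("male", "female"), side %in% c("left", "right"))
  chk <- function(v, what) {
    if (length(v) && is.null(names(v))) stop(what, " must be named by region id")
    if (any(v < 0) || any(v != round(v))) {
      stop(what, " must be non-negative integers")
    }
    stats::setNames(as.integer(v), names(v))
  }
  structure(list(sample_id = as.character(sample_id), sex = sex,
                 target = as.character(target), side = side,
                 starters = chk(starters, "starters"),
                 presynaptic = chk(presynaptic, "presynaptic")),
            class = "hemisphere_sample")
}

#' @export
print.hemisphere_sample <- function(x, ...) {
  cat(sprintf("hemisphere_sample %s (%s, %s, %s): %d starters, %d presynaptic\n",
              x$sample_id, x$sex, x$target, x$side,
              sum(x$starters), sum(x$presynaptic)))
  invisible(x)
}

#' Quality-control gate for one hemisphere sample
#'
#' Passes iff total starters >= `min_starters` (inclusive) AND the fraction
#' of starters inside the injection-target subtree is strictly greater than
#' `min_target_fraction` ("over 60%").
#'
#' @param sample a [hemisphere_sample()].
#' @param target_region_ids region ids forming the target subtree (e.g.
#'   from [region_subtree()]).
#' @param min_starters minimum total starter count (default 20, inclusive).
#' @param min_target_fraction strict lower bound on the in-target starter
#'   fraction (default 0.6).
#' @return list with `pass` (logical) and `reason` (string, `""` on pass).
#' @export
qc_pass <- function(sample, target_region_ids, min_starters = 20L,
                    min_target_fraction = 0.6) {
  stopifnot(inherits(sample, "hemisphere_sample"))
  total <- sum(sample$starters)
  if (total < min_starters) {
    return(list(pass = FALSE,
                reason = sprintf("minimum of %d starter cells not met (%d)",
                                 min_starters, total)))
  }
  in_target <- sum(sample$starters[names(sample$starters) %in%
                                     as.character(target_region_ids)])
  frac <- in_target / total
  if (!(frac > min_target_fraction)) {
    return(list(pass = FALSE,
                reason = sprintf(
                  "over %.0f%% of starters in target not met (%.1f%%)",
                  100 * min_target_fraction, 100 * frac)))
  }
  list(pass = TRUE, reason = "")
}

#' Compute PPS, FPR and starter-distribution metrics for one sample
#'
#' PPS (presynaptic per starter): region presynaptic count / total starters.
#' FPR (fraction per region): region presynaptic count / total presynaptic.
#' Starter distribution: region starter count / total starters. The
#' unassigned pseudo-region (id 0) participates in all denominators and
#' appears in the vectors, so FPR and starter distribution sum to exactly 1.
#'
#' @param sample a [hemisphere_sample()].
#' @return a `quant_metrics` list: `pps`, `fpr`, `starter_dist` (named
#'   vectors), `total_starters`, `total_presynaptic`.
#' @export
compute_metrics <- function(sample) {
  stopifnot(inherits(sample, "hemisphere_sample"))
  total_s <- sum(sample$starters)
  total_p <- sum(sample$presynaptic)
  if (total_s == 0) stop("PPS undefined: sample has zero starters")
  if (total_p == 0) stop("FPR undefined: sample has zero presynaptic cells")
  structure(list(
    pps = sample$presynaptic / total_s,
    fpr = sample$presynaptic / total_p,
    starter_dist = sample$starters / total_s,
    total_starters = total_s,
    total_presynaptic = total_p
  ), class = "quant_metrics")
}

#' Region-inclusion filter for hypothesis testing
#'
#' A region is included iff its mean presynaptic count is strictly greater
#' than `min_mean` in male samples OR in female samples ("averaging more
#' than 30 ... in either"). The unassigned pseudo-region is never included.
#'
#' @param samples list of [hemisphere_sample()] (>= 1 per sex).
#' @param min_mean strict mean-count threshold (default 30).
#' @return sorted integer vector of included region ids.
#' @export
region_inclusion <- function(samples, min_mean = 30) {
  sexes <- vapply(samples, `[[`, character(1), "sex")
  if (!all(c("male", "female") %in% sexes)) {
    stop("need at least one sample of each sex")
  }
  rids <- sort(unique(unlist(lapply(samples, function(s) names(s$presynaptic)))))
  rids <- setdiff(rids, as.character(UNASSIGNED_ID))
  count_of <- function(s, rid) {
    v <- s$presynaptic[[rid]]
    if (is.null(v)) 0L else v
  }
  keep <- vapply(rids, function(rid) {
    m <- mean(vapply(samples[sexes == "male"], count_of, numeric(1), rid))
    f <- mean(vapply(samples[sexes == "female"], count_of, numeric(1), rid))
    m > min_mean || f > min_mean
  }, logical(1))
  sort(as.integer(rids[keep]))
}

#' Build a QC-passing cohort from region-assigned cell calls
#'
#' Pools each hemisphere's calls over its sections inside the atlas AP
#' window, tallies starter and presynaptic counts per region, applies the
#' QC gate, and returns passing samples plus an exclusion log.
#'
#' @param calls data.frame of region-assigned cell calls with columns
#'   `sample_id`, `sex`, `target`, `side`, `ap_mm`, `region_id`, `kind`
#'   (`starter` / `presynaptic` / `helper_only`).
#' @param atlas a `region_atlas` (provides the AP window and target
#'   subtrees).
#' @param target_region_ids optional named list mapping target labels to
#'   subtree-root region ids; by default each target label is looked up as
#'   an acronym in the atlas.
#' @param min_starters,min_target_fraction QC parameters, see [qc_pass()].
#' @return list with `samples` (passing [hemisphere_sample()]s) and
#'   `exclusions` (data.frame `sample_id`, `reason`).
#' @export
build_cohort <- function(calls, atlas, target_region_ids = NULL,
                         min_starters = 20L, min_target_fraction = 0.6) {
  stopifnot(inherits(atlas, "region_atlas"))
  req <- c("sample_id", "sex", "target", "side", "ap_mm", "region_id", "kind")
  if (nrow(calls) == 0) {
    return(list(samples = list(),
                exclusions = data.frame(sample_id = character(0),
                                        reason = character(0))))
  }
  stopifnot(all(req %in% names(calls)))
  meta <- unique(calls[, c("sample_id", "sex", "target", "side")])
  if (anyDuplicated(meta$sample_id)) {
    stop("inconsistent sex/target/side for duplicated sample_id: ",
         paste(meta$sample_id[duplicated(meta$sample_id)], collapse = ", "))
  }
  calls <- calls[in_ap_window(atlas, calls$ap_mm), , drop = FALSE]

  subtree_for <- function(target) {
    if (!is.null(target_region_ids) && target %in% names(target_region_ids)) {
      return(region_subtree(atlas, target_region_ids[[target]]))
    }
    hit <- atlas$nodes$id[atlas$nodes$acronym == target]
    if (length(hit) != 1) {
      stop("cannot resolve target '", target, "' to an atlas region; ",
           "pass target_region_ids")
    }
    region_subtree(atlas, hit)
  }

  samples <- list(); excl <- list()
  for (i in seq_len(nrow(meta))) {
    sid <- meta$sample_id[i]
    sc <- calls[calls$sample_id == sid, , drop = FALSE]
    tally <- function(kind) {
      k <- sc[sc$kind == kind, , drop = FALSE]
      if (nrow(k) == 0) return(stats::setNames(integer(0), character(0)))
      tab <- table(k$region_id)
      stats::setNames(as.integer(tab), names(tab))
    }
    smp <- hemisphere_sample(sid, meta$sex[i], meta$target[i], meta$side[i],
                             starters = tally("starter"),
                             presynaptic = tally("presynaptic"))
    qc <- qc_pass(smp, subtree_for(meta$target[i]),
                  min_starters = min_starters,
                  min_target_fraction = min_target_fraction)
    if (qc$pass) {
      samples[[length(samples) + 1]] <- smp
    } else {
      excl[[length(excl) + 1]] <- data.frame(sample_id = sid, reason = qc$reason)
    }
  }
  list(samples = samples,
       exclusions = if (length(excl)) do.call(rbind, excl)
                    else data.frame(sample_id = character(0), reason = character(0)))
}

#' Write / read a cohort as CSV (long format)
#'
#' Columns: sample_id, sex, target, side, region_id, starters, presynaptic.
#' @param samples list of [hemisphere_sample()].
#' @param path CSV path.
#' @return `path` (write) or list of samples (read), invisibly for write.
#' @export
write_cohort_csv <- function(samples, path) {
  rows <- lapply(samples, function(s) {
    rids <- sort(unique(c(names(s$starters), names(s$presynaptic))))
    g <- function(v, r) if (r %in% names(v)) v[[r]] else 0L
    data.frame(sample_id = s$sample_id, sex = s$sex, target = s$target,
               side = s$side, region_id = as.integer(rids),
               starters = vapply(rids, g, integer(1), v = s$starters),
               presynaptic = vapply(rids, g, integer(1), v = s$presynaptic))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$sample_id), function(d) {
    hemisphere_sample(d$sample_id[1], d$sex[1], d$target[1], d$side[1],
                      starters = stats::setNames(d$starters, d$region_id),
                      presynaptic = stats::setNames(d$presynaptic, d$region_id))
  })
}
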