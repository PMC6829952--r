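#' Relative Z-value of a pathway
#'
#' The pathway-activity statistic `sigma_Z = Z_up - Z_down`: the signed
#' enrichment Z of the pathway among up-regulated genes minus that among
#' down-regulated genes. Positive values mean net activation.
#'
#' @param z_up,z_down Signed enrichment Z-values (finite).
#' @return `z_up - z_down`.
#' @export
sigma_z <- function(z_up, z_down) {
  stopifnot(all(is.finite(z_up)), all(is.finite(z_down)))
  z_up - z_down
}

#' Classify pathway activity from sigma-Z
#'
#' A pathway is active when `sigma_Z > 0` and significantly active when
#' `sigma_Z >= threshold` (the 1.96 boundary itself counts as significant);
#' symmetrically inactive / significantly inactive for non-positive values.
#'
#' @param x sigma-Z value(s).
#' @param threshold Significance threshold (default 1.96, the two-sided
#'   5 percent normal quantile, rounded as conventionally printed).
#' @return Character vector in `{"significantly_active", "active",
#'   "inactive", "significantly_inactive"}`.
#' @export
classify_activity <- function(x, threshold = 1.96) {
  stopifnot(threshold > 0)
  out <- character(length(x))
  out[x >= threshold] <- "significantly_active"
  out[x > 0 & x < threshold] <- "active"
  out[x <= 0 & x > -threshold] <- "inactive"
  out[x <= -threshold] <- "significantly_inactive"
  out
}

#' Pathway activity table from directional enrichment
#'
#' Reshapes an [enrich_all()] table into one row per (bin, contrast) with
#' `Z_up`, `Z_down`, `sigma_Z` and the activity status. A (bin, contrast)
#' missing one direction's cell uses `Z = 0` for that direction (the
#' continuous limit of an empty DE set: `n = 0` gives `p = 1`, `Z = 0`).
#'
#' @param enrichment Data frame from [enrich_all()].
#' @param threshold See [classify_activity()].
#' @return Data frame `bincode`, `bin_name`, `contrast_id`, `system`,
#'   `test`, `ref`, `Z_up`, `Z_down`, `sigma_Z`, `status`. `system`,
#'   `test`, `ref` are carried through when present in the contrast ids
#'   via `attr(enrichment, "contrasts")`, otherwise parsed from
#'   `contrast_id` (`"<test>_vs_<ref>"`).
#' @export
activity_table <- function(enrichment, threshold = 1.96) {
  key <- unique(enrichment[, c("bincode", "bin_name", "contrast_id")])
  zu <- enrichment[enrichment$direction == "up", ]
  zd <- enrichment[enrichment$direction == "down", ]
  idx <- function(tab, key) {
    m <- match(paste(key$bincode, key$contrast_id),
               paste(tab$bincode, tab$contrast_id))
    z <- tab$Z[m]
    z[is.na(z)] <- 0
    z
  }
  key$Z_up <- idx(zu, key)
  key$Z_down <- idx(zd, key)
  key$sigma_Z <- sigma_z(key$Z_up, key$Z_down)
  key$status <- classify_activity(key$sigma_Z, threshold)
  parts <- strsplit(key$contrast_id, "_vs_", fixed = TRUE)
  key$test <- vapply(parts, `[`, "", 1)
  key$ref <- vapply(parts, `[`, "", 2)
  rownames(key) <- NULL
  key[, c("bincode", "bin_name", "contrast_id", "test", "ref",
          "Z_up", "Z_down", "sigma_Z", "status")]
}

#' Quadrant concordance between the two contrast systems
#'
#' For every stage beyond the second and every bin present in both systems,
#' places the point `(x, y)` with `x` the sigma-Z from the fixed-reference
#' system and `y` the sigma-Z from the continuous system at that stage,
#' assigns its quadrant, and colours it:
#'
#' * `green` — neither coordinate significant (`|x| < t` and `|y| < t`;
#'   the boundary `|x| = t` counts as significant);
#' * `blue` — at least one coordinate significant and the point lies in
#'   quadrant I or III (both coordinates strictly positive or both strictly
#'   negative), i.e. the two systems agree in direction;
#' * `red` — at least one coordinate significant, direction not concordant.
#'
#' @param fixed_activity,continuous_activity Activity tables from
#'   [activity_table()] for the fixed and continuous systems.
#' @param stages Stage labels to evaluate; default every test stage shared
#'   by the two systems whose fixed and continuous contrasts differ.
#' @param threshold Significance threshold (default 1.96).
#' @return Data frame `bincode`, `stage`, `x`, `y`, `quadrant`,
#'   `color_class`.
#' @export
concordance <- function(fixed_activity, continuous_activity, stages = NULL,
                        threshold = 1.96) {
  if (is.null(stages)) {
    stages <- intersect(unique(fixed_activity$test),
                        unique(continuous_activity$test))
    # drop stages where the two systems share the same reference (the first
    # post-baseline stage): there x == y by construction
    same_ref <- vapply(stages, function(st) {
      fr <- unique(fixed_activity$ref[fixed_activity$test == st])
      cr <- unique(continuous_activity$ref[continuous_activity$test == st])
      length(fr) == 1 && length(cr) == 1 && fr == cr
    }, TRUE)
    stages <- stages[!same_ref]
  }
  rows <- list()
  for (st in stages) {
    fx <- fixed_activity[fixed_activity$test == st, ]
    cy <- continuous_activity[continuous_activity$test == st, ]
    common <- intersect(fx$bincode, cy$bincode)
    only <- c(setdiff(fx$bincode, cy$bincode), setdiff(cy$bincode, fx$bincode))
    if (length(only))
      warning("stage ", st, ": bin(s) present in one system only, excluded: ",
              paste(only, collapse = ", "), call. = FALSE)
    x <- fx$sigma_Z[match(common, fx$bincode)]
    y <- cy$sigma_Z[match(common, cy$bincode)]
    quadrant <- ifelse(x > 0 & y > 0, "I",
                ifelse(x < 0 & y > 0, "II",
                ifelse(x < 0 & y < 0, "III",
                ifelse(x > 0 & y < 0, "IV", "axis"))))
    significant <- abs(x) >= threshold | abs(y) >= threshold
    color <- ifelse(!significant, "green",
                    ifelse(quadrant %in% c("I", "III"), "blue", "red"))
    rows[[length(rows) + 1L]] <- data.frame(
      bincode = common, stage = st, x = x, y = y,
      quadrant = quadrant, color_class = color, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pathway activation timetable
#'
#' Derives, per bin, the onset stage (first stage, on the fixed-reference
#' system, at which the pathway is significantly active), the peak stage
#' (global argmax of sigma-Z; first stage on ties) and the offset stage
#' (first stage after onset with `sigma_Z <= 0`), then orders all bins by
#' onset stage index, ties broken by peak stage index, remaining ties by
#' bincode. Bins never significantly active get no onset and sort last.
#'
#' @param fixed_activity Activity table ([activity_table()]) of the
#'   fixed-reference system.
#' @param stage_order Stage labels in time order (the baseline first).
#' @param threshold Significance threshold (default 1.96).
#' @return Data frame `bincode`, `bin_name`, `onset`, `peak`, `offset`,
#'   `rank`, one row per bin, ordered by `rank`. Stage columns hold stage
#'   labels or `NA`.
#' @export
activation_timetable <- function(fixed_activity, stage_order,
                                 threshold = 1.96) {
  stage_order <- as.character(stage_order)
  test_stages <- stage_order[-1]
  bins <- unique(fixed_activity[, c("bincode", "bin_name")])
  bins <- bins[order_bincodes(bins$bincode), , drop = FALSE]

  res <- lapply(seq_len(nrow(bins)), function(i) {
    bc <- bins$bincode[i]
    ba <- fixed_activity[fixed_activity$bincode == bc, ]
    traj <- ba$sigma_Z[match(test_stages, ba$test)]
    if (anyNA(traj))
      stop("bin ", bc, ": fixed-system activity missing for stage(s) ",
           paste(test_stages[is.na(traj)], collapse = ", "), call. = FALSE)
    onset_i <- which(traj >= threshold)[1]
    peak_i <- which.max(traj)
    offset_i <- if (!is.na(onset_i)) {
      after <- which(traj <= 0 & seq_along(traj) > onset_i)[1]
      after
    } else NA_integer_
    data.frame(bincode = bc, bin_name = bins$bin_name[i],
               onset_i = ifelse(is.na(onset_i), NA_integer_, onset_i),
               peak_i = peak_i,
               offset_i = ifelse(is.na(offset_i), NA_integer_, offset_i),
               stringsAsFactors = FALSE)
  })
  tt <- do.call(rbind, res)
  # bincode tie-break must follow numeric bin order, not lexicographic
  pos <- integer(nrow(tt))
  pos[order_bincodes(tt$bincode)] <- seq_len(nrow(tt))
  ord <- order(ifelse(is.na(tt$onset_i), Inf, tt$onset_i), tt$peak_i, pos)
  tt <- tt[ord, ]
  tt$rank <- seq_len(nrow(tt))
  tt$onset <- ifelse(is.na(tt$onset_i), NA_character_, test_stages[tt$onset_i])
  tt$peak <- test_stages[tt$peak_i]
  tt$offset <- ifelse(is.na(tt$offset_i), NA_character_, test_stages[tt$offset_i])
  rownames(tt) <- NULL
  tt[, c("bincode", "bin_name", "onset", "peak", "offset", "rank")]
}
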