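#' Default AOI rectangle map
#'
#' Four named rectangles (female character, male character, object1,
#' object2) in screen pixels on a 1280 x 1024 display, one per quadrant,
#' separated by gaps so the rectangles are disjoint.
#'
#' @return data.table with columns aoi, x0, y0, x1, y1.
#' @export
default_aoi_map <- function() {
  data.table::data.table(
    aoi = c("female", "male", "object1", "object2"),
    x0 = c(64, 704, 64, 704),
    y0 = c(112, 112, 552, 552),
    x1 = c(576, 1216, 576, 1216),
    y1 = c(472, 472, 912, 912)
  )
}

#' Read a fixation report
#'
#' Reads a tab-separated fixation report (one row per fixation, Data-Viewer
#' style) and validates it. Rows whose times are non-numeric or whose end
#' does not exceed their start are rejected and reported via a message with
#' their line numbers.
#'
#' @param path Path to a TSV file.
#' @param col_map Named character vector mapping canonical names
#'   (participant, trial, start, end, x, y, aoi) to the file's column
#'   names; defaults to identity. x/y or aoi may be absent, but not both.
#' @return data.table of validated fixation records; the number of rejected
#'   rows is attached as attribute `n_rejected`.
#' @export
read_fixation_report <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- data.table::fread(path, sep = "\t", colClasses = "character")
  defaults <- c(participant = "participant", trial = "trial",
                start = "start", end = "end", x = "x", y = "y", aoi = "aoi")
  cm <- defaults
  if (!is.null(col_map)) cm[names(col_map)] <- col_map
  for (f in c("participant", "trial", "start", "end"))
    if (!cm[[f]] %in% names(raw))
      stop("fixation report is missing required column '", cm[[f]],
           "' (", f, ")")
  has_xy <- all(cm[c("x", "y")] %in% names(raw))
  has_aoi <- cm[["aoi"]] %in% names(raw)
  if (!has_xy && !has_aoi)
    stop("fixation report needs either coordinate columns ('", cm[["x"]],
         "', '", cm[["y"]], "') or an AOI column ('", cm[["aoi"]], "')")
  pid <- raw[[cm[["participant"]]]]
  pid_num <- suppressWarnings(as.numeric(pid))
  out <- data.table::data.table(
    participant = if (anyNA(pid_num)) pid else pid_num,
    trial = suppressWarnings(as.numeric(raw[[cm[["trial"]]]])),
    start = suppressWarnings(as.numeric(raw[[cm[["start"]]]])),
    end = suppressWarnings(as.numeric(raw[[cm[["end"]]]])))
  if (has_xy) {
    out[, x := suppressWarnings(as.numeric(raw[[cm[["x"]]]]))]
    out[, y := suppressWarnings(as.numeric(raw[[cm[["y"]]]]))]
  }
  if (has_aoi) out[, aoi := raw[[cm[["aoi"]]]]]
  bad_time <- which(is.na(out$start) | is.na(out$end) | is.na(out$trial))
  bad_order <- which(!is.na(out$start) & !is.na(out$end) &
                       (out$end <= out$start | out$start < 0))
  bad <- sort(union(bad_time, bad_order))
  if (length(bad)) {
    message(length(bad), " fixation row(s) rejected (line ",
            paste(bad + 1L, collapse = ", "), "): non-numeric time or ",
            "end <= start or negative time")
    out <- out[-bad]
  }
  data.table::setattr(out, "n_rejected", length(bad))
  out[]
}

#' Write a fixation report
#'
#' @param fixations data.table of fixation records.
#' @param path Output TSV path.
#' @export
write_fixation_report <- function(fixations, path) {
  data.table::fwrite(fixations, path, sep = "\t")
  invisible(path)
}

#' Assign fixations to areas of interest
#'
#' Point-in-rectangle lookup with half-open rectangles
#' `[x0, x1) x [y0, y1)`: a point on a shared edge of two touching
#' rectangles belongs to exactly one. Points outside all rectangles map to
#' "elsewhere".
#'
#' @param x,y Numeric vectors of gaze coordinates.
#' @param aoi_map Rectangle table as in [default_aoi_map()].
#' @param strict If TRUE, a point inside two (overlapping) rectangles is an
#'   error; otherwise the first matching rectangle in `aoi_map` order wins.
#' @return Character vector of AOI labels.
#' @export
assign_aoi <- function(x, y, aoi_map = default_aoi_map(), strict = FALSE) {
  if (any(aoi_map$x1 <= aoi_map$x0) || any(aoi_map$y1 <= aoi_map$y0))
    stop("AOI rectangles must have positive area")
  n <- length(x)
  hit <- matrix(FALSE, n, nrow(aoi_map))
  for (j in seq_len(nrow(aoi_map)))
    hit[, j] <- x >= aoi_map$x0[j] & x < aoi_map$x1[j] &
      y >= aoi_map$y0[j] & y < aoi_map$y1[j]
  nh <- rowSums(hit)
  if (strict && any(nh > 1))
    stop("ambiguous AOI assignment: point inside overlapping rectangles")
  lab <- rep("elsewhere", n)
  any_hit <- nh > 0
  lab[any_hit] <- aoi_map$aoi[max.col(hit[any_hit, , drop = FALSE],
                                      ties.method = "first")]
  lab
}

#' Expand fixations to 1-ms samples and aggregate into bins
#'
#' For one trial: each 1-ms sample inside a fixation (sample at time t
#' belongs to a fixation iff `t` is in `[start, end)`) is credited to that
#' fixation's AOI; samples covered by no fixation count as elsewhere. The
#' samples are aggregated into consecutive `bin_ms` windows tiling
#' `[window[1], window[2])` ms relative to `noun_onset`. Implemented by
#' interval arithmetic, which equals the literal indicator-vector
#' computation exactly for integer-aligned times.
#'
#' @param fixations data.table with columns start, end, aoi (one trial,
#'   trial clock in ms).
#' @param noun_onset Critical-noun onset on the trial clock (ms).
#' @param window Analysis window `c(lo, hi)` in ms relative to noun onset;
#'   both bounds must be multiples of `bin_ms`.
#' @param bin_ms Bin width in ms.
#' @return data.table with one row per bin: bin (1-based index), bin_start,
#'   bin_end (ms relative to noun onset), sample counts female, male,
#'   object1, object2, elsewhere (gaps plus elsewhere-labelled fixations),
#'   and n_valid (samples covered by any fixation).
#' @export
expand_and_bin <- function(fixations, noun_onset,
                           window = c(-2000, 1000), bin_ms = 100) {
  if (any(window %% bin_ms != 0))
    stop("window bounds must be multiples of bin_ms")
  n_bins <- as.integer(diff(window) / bin_ms)
  bins <- data.table::data.table(
    bin = seq_len(n_bins),
    bin_start = window[1] + (seq_len(n_bins) - 1L) * bin_ms)
  bins[, bin_end := bin_start + bin_ms]
  lv <- aoi_levels()
  counts <- matrix(0, n_bins, length(lv), dimnames = list(NULL, lv))
  n_valid <- numeric(n_bins)
  if (nrow(fixations)) {
    s <- pmax(fixations$start - noun_onset, window[1])
    e <- pmin(fixations$end - noun_onset, window[2])
    keep <- e > s
    if (any(keep)) {
      s <- s[keep]; e <- e[keep]; a <- fixations$aoi[keep]
      ov <- pmax(outer(e, bins$bin_end, pmin) -
                   outer(s, bins$bin_start, pmax), 0)
      for (j in seq_along(lv))
        if (any(a == lv[j]))
          counts[, j] <- colSums(ov[a == lv[j], , drop = FALSE])
      n_valid <- colSums(ov)
    }
  }
  counts[, "elsewhere"] <- bin_ms - rowSums(counts[, lv[1:4], drop = FALSE])
  out <- cbind(bins, data.table::as.data.table(counts))
  out[, n_valid := n_valid]
  out[]
}

#' Bin a whole experiment's fixations
#'
#' Applies [expand_and_bin()] to every experimental trial, assigning AOIs
#' from coordinates when no label column is present, and attaches the
#' trial's condition columns.
#'
#' @param fixations data.table of fixation records (participant, trial,
#'   start, end, and aoi or x/y).
#' @param trials Trial metadata with participant, trial, noun_onset and
#'   condition columns.
#' @param aoi_map Rectangle table for coordinate-based AOI assignment.
#' @param window,bin_ms As in [expand_and_bin()].
#' @return data.table: one row per trial x bin with condition columns and
#'   per-AOI sample counts.
#' @export
bin_experiment <- function(fixations, trials, aoi_map = default_aoi_map(),
                           window = c(-2000, 1000), bin_ms = 100) {
  fx <- data.table::as.data.table(fixations)
  if (!"aoi" %in% names(fx)) {
    fx <- data.table::copy(fx)
    fx[, aoi := assign_aoi(x, y, aoi_map)]
  }
  tri <- data.table::as.data.table(trials)
  fx <- merge(fx, tri[, .(participant, trial, noun_onset)],
              by = c("participant", "trial"))
  if (any(window %% bin_ms != 0))
    stop("window bounds must be multiples of bin_ms")
  n_bins <- as.integer(diff(window) / bin_ms)
  # vectorized interval arithmetic over all trials at once; equals the
  # per-trial expand_and_bin() exactly (property-tested)
  fx[, `:=`(rs = pmax(start - noun_onset, window[1]),
            re = pmin(end - noun_onset, window[2]))]
  fx <- fx[re > rs]
  fx[, `:=`(b1 = floor((rs - window[1]) / bin_ms) + 1L,
            b2 = floor((re - window[1] - 1e-9) / bin_ms) + 1L)]
  nb <- fx$b2 - fx$b1 + 1L
  idx <- rep(seq_len(nrow(fx)), nb)
  long <- fx[idx, .(participant, trial, aoi, rs, re)]
  long[, bin := fx$b1[idx] + sequence(nb) - 1L]
  long[, ov := pmin(re, window[1] + bin * bin_ms) -
         pmax(rs, window[1] + (bin - 1L) * bin_ms)]
  agg <- long[, .(ov = sum(ov)), by = .(participant, trial, bin, aoi)]
  wide <- data.table::dcast(agg, participant + trial + bin ~ aoi,
                            value.var = "ov", fill = 0)
  for (a in aoi_levels())
    if (!a %in% names(wide)) wide[, (a) := 0]
  # complete grid: every trial gets all bins, empty ones all-elsewhere
  grid <- tri[, .(participant, trial)][
    , data.table::data.table(bin = seq_len(n_bins)),
    by = .(participant, trial)]
  out <- merge(grid, wide, by = c("participant", "trial", "bin"),
               all.x = TRUE)
  for (a in aoi_levels())
    data.table::set(out, which(is.na(out[[a]])), a, 0)
  out[, n_valid := female + male + object1 + object2 + elsewhere]
  out[, elsewhere := bin_ms - (female + male + object1 + object2)]
  out[, `:=`(bin_start = window[1] + (bin - 1L) * bin_ms)]
  out[, bin_end := bin_start + bin_ms]
  out <- merge(out, tri[, .(participant, trial, item_id, list_id,
                            occupation_stereotype, action_stereotype,
                            agent_gender)],
               by = c("participant", "trial"))
  data.table::setorder(out, participant, trial, bin)
  data.table::setcolorder(out, c("participant", "trial", "bin",
                                 "bin_start", "bin_end", "female", "male",
                                 "object1", "object2", "elsewhere",
                                 "n_valid"))
  out[]
}
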