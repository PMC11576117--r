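#' Observation-event tables
#'
#' The CTHMM likelihood consumes one timestamped evidence item per row:
#' an artificial birth observation pinning state 1 at age 0, clinical visits
#' carrying a feature vector, exactly observed deaths, and interval-censored
#' deaths known only to fall between the last visit and an upper bound.
#'
#' @param df A data frame with columns `patient_id`, `kind` (one of
#'   `"birth"`, `"visit"`, `"death_exact"`, `"death_interval"`), `age`
#'   (years; visits and exact deaths), `lo`, `hi` (years; interval deaths),
#'   plus one numeric column per feature for visit rows.
#' @param feature_names Character vector naming the feature columns.
#' @return The validated data frame with class `hd_events` and a
#'   `features` attribute.
#' @export
as_hd_events <- function(df, feature_names) {
  df <- as.data.frame(df)
  need <- c("patient_id", "kind", "age", "lo", "hi", feature_names)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("events table is missing column(s): ", paste(miss, collapse = ", "))
  kinds <- c("birth", "visit", "death_exact", "death_interval")
  if (!all(df$kind %in% kinds))
    stop("unknown event kind(s): ",
         paste(unique(setdiff(df$kind, kinds)), collapse = ", "))
  tkey <- event_time(df)
  ord <- order(match(df$patient_id, unique(df$patient_id)), tkey,
               match(df$kind, kinds))
  df <- df[ord, , drop = FALSE]
  for (pid in unique(df$patient_id)) {
    rows <- df[df$patient_id == pid, , drop = FALSE]
    deaths <- rows$kind %in% c("death_exact", "death_interval")
    if (sum(deaths) > 1L)
      stop("patient ", pid, " has more than one death event")
    vis <- rows$kind == "visit"
    if (any(vis)) {
      va <- rows$age[vis]
      if (is.unsorted(va, strictly = TRUE))
        stop("patient ", pid, ": visit ages must be strictly increasing")
      if (any(!is.finite(as.matrix(rows[vis, feature_names, drop = FALSE]))))
        stop("patient ", pid, ": visit features must be finite")
      if (any(deaths)) {
        dstart <- if (rows$kind[deaths] == "death_exact")
          rows$age[deaths] else rows$lo[deaths]
        if (dstart < max(va) - 1e-9)
          stop("patient ", pid, ": death must not precede the last visit")
      }
    }
    if (any(rows$kind == "death_interval")) {
      iv <- rows[rows$kind == "death_interval", c("lo", "hi")]
      if (any(!is.finite(unlist(iv))) || iv$hi < iv$lo)
        stop("patient ", pid, ": invalid death interval")
    }
  }
  rownames(df) <- NULL
  attr(df, "features") <- feature_names
  class(df) <- c("hd_events", "data.frame")
  df
}

# Chronological sort key for events (birth first, interval death at its
# lower bound).
event_time <- function(df) {
  ifelse(df$kind == "birth", -Inf,
         ifelse(df$kind == "death_interval", df$lo, df$age))
}

#' @export
print.hd_events <- function(x, ...) {
  cat("hd_events:", nrow(x), "events,",
      length(unique(x$patient_id)), "patients; features:",
      paste(attr(x, "features"), collapse = ", "), "\n")
  NextMethod()
}

# Pack an hd_events table into the flat arrays the C++ forward pass uses.
pack_events <- function(events, feature_names) {
  stopifnot(inherits(events, "hd_events"))
  miss <- setdiff(feature_names, names(events))
  if (length(miss))
    stop("events lack feature column(s): ", paste(miss, collapse = ", "))
  pid <- match(events$patient_id, unique(events$patient_id))
  kind <- match(events$kind, c("birth", "visit", "death_exact",
                               "death_interval"))
  feat <- as.matrix(events[, feature_names, drop = FALSE])
  feat[!is.finite(feat)] <- 0
  list(
    offsets = as.integer(c(0L, cumsum(tabulate(pid)))),
    kind = as.integer(kind),
    age = ifelse(is.finite(events$age), events$age, 0),
    lo = ifelse(is.finite(events$lo), events$lo, 0),
    hi = ifelse(is.finite(events$hi), events$hi, 0),
    feat = feat,
    patient_ids = unique(events$patient_id))
}
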