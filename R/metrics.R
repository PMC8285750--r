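#' Mean search time of a session
#'
#' Arithmetic mean of the search time over found targets only; targets that
#' expired unfound carry no search time and are excluded.
#'
#' @param session A [run_session()] record, or a data.frame of target
#'   events with columns `found` and `search_time_s`.
#' @return Mean search time in seconds.
#' @export
mean_search_time <- function(session) {
  ev <- session_events(session)
  st <- ev$search_time_s[ev$found %in% TRUE]
  if (length(st) == 0L) {
    stop("mean search time is undefined: no found targets", call. = FALSE)
  }
  mean(st)
}

#' Mean search time per hemispace
#'
#' Means computed separately over found targets appearing in the left and
#' right hemispace. A hemispace with no found target yields `NA` (an
#' explicit missing value, not an error): the quantity is simply not
#' observable there.
#'
#' @inheritParams mean_search_time
#' @return Named numeric vector `c(left = ..., right = ...)`, seconds.
#' @export
hemispace_search_times <- function(session) {
  ev <- session_events(session)
  one <- function(side) {
    st <- ev$search_time_s[ev$found %in% TRUE & ev$hemispace == side]
    if (length(st) == 0L) NA_real_ else mean(st)
  }
  c(left = one("left"), right = one("right"))
}

session_events <- function(session) {
  ev <- if (inherits(session, "session_record")) session$events else session
  if (!is.data.frame(ev) ||
      !all(c("found", "search_time_s", "hemispace") %in% names(ev))) {
    stop("expected a session_record or a target-event data.frame",
         call. = FALSE)
  }
  ev
}
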