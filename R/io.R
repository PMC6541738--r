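#' Write / read cytometry event tables as CSV
#'
#' Event tables are serialized with the fixed header
#' `sample_id,condition_atc_nM,condition_iptg_uM,replicate,is_control,fsc_area,ssc_height,fl1_area[,fl2_area]`.
#'
#' @param events An event table (see [simulate_flow_sample()]).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_event_csv <- function(events, path) {
  cols <- c("sample_id", "condition_atc_nM", "condition_iptg_uM",
            "replicate", "is_control", "fsc_area", "ssc_height", "fl1_area")
  if ("fl2_area" %in% names(events)) cols <- c(cols, "fl2_area")
  missing <- setdiff(cols, names(events))
  if (length(missing)) {
    stop("event table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(events[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_csv
#' @return `read_event_csv()`: the event table `data.frame`.
#' @export
read_event_csv <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition_atc_nM", "condition_iptg_uM",
            "replicate", "is_control", "fsc_area", "ssc_height", "fl1_area")
  missing <- setdiff(need, names(ev))
  if (length(missing)) {
    stop("not an event CSV (missing columns: ",
         paste(missing, collapse = ", "), ")", call. = FALSE)
  }
  num <- intersect(c("fsc_area", "ssc_height", "fl1_area", "fl2_area"),
                   names(ev))
  bad <- !vapply(ev[num], function(x) all(is.finite(x)), logical(1))
  if (any(bad)) {
    stop("non-finite values in column(s): ", paste(num[bad], collapse = ", "),
         call. = FALSE)
  }
  ev
}
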