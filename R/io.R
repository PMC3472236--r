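# On-disk formats: tab-delimited tables whose column names carry the unit
# (time_s, current_A, ...) plus a YAML metadata sidecar (<prefix>.meta.yaml)
# holding protocol, noise and ground-truth provenance. Plain text only.

#' Write and read synthetic trace sets
#'
#' `write_trace_set()` writes `<prefix>.tsv` (columns `sweep`, `time_s`,
#' `v_command_V`, `current_A`) and `<prefix>.meta.yaml` (per-sweep metadata
#' and generator ground truth). `read_trace_set()` reverses it.
#'
#' @param ts A `kv_trace_set` (see [make_voltage_clamp_dataset()]).
#' @param prefix Path prefix (no extension).
#' @return `write_trace_set()` returns `prefix` invisibly;
#'   `read_trace_set()` a `kv_trace_set`.
#' @export
write_trace_set <- function(ts, prefix) {
  stopifnot(inherits(ts, "kv_trace_set"))
  d <- ts$data
  readr::write_tsv(
    tibble(sweep = d$sweep, time_s = d$time,
           v_command_V = d$v_command, current_A = d$current),
    paste0(prefix, ".tsv"))
  yaml::write_yaml(
    list(sweeps = lapply(seq_len(nrow(ts$sweeps)), function(i) {
      as.list(ts$sweeps[i, ])
    }),
    truth = ts$truth),
    paste0(prefix, ".meta.yaml"), precision = 17)
  invisible(prefix)
}

#' @rdname write_trace_set
#' @export
read_trace_set <- function(prefix) {
  d <- readr::read_tsv(paste0(prefix, ".tsv"),
                       show_col_types = FALSE)
  meta <- yaml::read_yaml(paste0(prefix, ".meta.yaml"))
  structure(list(
    data = tibble(sweep = d$sweep, time = d$time_s,
                  v_command = d$v_command_V, current = d$current_A),
    sweeps = dplyr::bind_rows(lapply(meta$sweeps, as_tibble)),
    truth = meta$truth
  ), class = "kv_trace_set")
}

#' Write a simulation result as a delimited table with sidecar
#'
#' Columns are unit-suffixed (`time_s`, `v_V`, currents in amperes); the
#' sidecar records mode, the full cell config and provenance fields.
#'
#' @param sim A `kv_sim` result.
#' @param prefix Path prefix.
#' @param provenance Optional named list merged into the sidecar.
#' @return `prefix`, invisibly.
#' @export
write_simulation <- function(sim, prefix, provenance = list()) {
  stopifnot(inherits(sim, "kv_sim"))
  out <- as_tibble(sim)
  names(out)[names(out) == "time"] <- "time_s"
  names(out)[names(out) == "v"] <- "v_V"
  ic <- grepl("^i_", names(out))
  names(out)[ic] <- paste0(names(out)[ic], "_A")
  readr::write_tsv(out, paste0(prefix, ".tsv"))
  side <- c(list(mode = attr(sim, "mode"),
                 cell = cell_to_config(attr(sim, "cell"))),
            provenance)
  yaml::write_yaml(side, paste0(prefix, ".meta.yaml"), precision = 17)
  invisible(prefix)
}
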