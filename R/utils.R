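# Classed conditions so the command-line wrapper can map failures to
# exit codes (2 config, 3 data, 4 numeric).
stop_config <- function(...)
  stop(errorCondition(paste0(...),
                      class = c("dementialm_config_error", "error",
                                "condition")))

stop_data <- function(...)
  stop(errorCondition(paste0(...),
                      class = c("dementialm_data_error", "error",
                                "condition")))

`%||%` <- function(a, b) if (is.null(a)) b else a
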