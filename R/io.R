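# Structured-text configuration I/O (YAML) and annotated TSV writers.

.reduced_config_keys <- c("glut1", "glut2", "gk", "volume_per_1e5_cells")

#' Read a model configuration file
#'
#' Reads a YAML key-value configuration.  When `required` keys are given,
#' each must be present (at the top level, or dotted paths such as
#' `"gk.vmax_gk"` for nested keys); a missing key raises an error naming
#' it.  Malformed YAML is reported with the parser's line/column message.
#'
#' @param path File path.
#' @param required Character vector of required keys.
#' @return Named list.
#' @export
read_config <- function(path, required = character()) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) {
                    stop("malformed config '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  for (key in required) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    node <- cfg
    for (p in parts) {
      if (!is.list(node) || is.null(node[[p]])) {
        stop("config '", path, "' is missing required key: ", key,
             call. = FALSE)
      }
      node <- node[[p]]
    }
  }
  cfg
}

#' Write a configuration file
#'
#' Writes a named list as YAML, preceded by comment lines (units and
#' provenance).  Numbers are written with 17 significant digits so that a
#' write/read round trip is lossless.
#'
#' @param config Named list.
#' @param path Output path.
#' @param comments Character vector of comment lines (without the leading
#'   `#`).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path, comments = character()) {
  txt <- yaml::as.yaml(config, precision = 17)
  header <- if (length(comments)) paste0("# ", comments, collapse = "\n")
  writeLines(c(header, txt), path, sep = "\n")
  invisible(path)
}

#' Serialise reduced-model parameters to a config list
#'
#' @param params A [reduced_model_params()] object.
#' @return Nested named list suitable for [write_config()].
#' @export
params_to_config <- function(params) {
  stopifnot(inherits(params, "reduced_model_params"))
  list(
    glut1 = list(km = params$glut1$km,
                 vmax_normal = params$glut1$vmax_normal,
                 epsilon = params$glut1$epsilon),
    glut2 = list(km = params$glut2$km,
                 vmax_normal = params$glut2$vmax_normal,
                 epsilon = params$glut2$epsilon),
    gk = list(s_half = params$gk$s_half,
              hill_exponent = params$gk$hill_exponent,
              vmax_gk = params$gk$vmax_gk),
    volume_per_1e5_cells = params$volume_per_1e5_cells
  )
}

#' Build reduced-model parameters from a config list
#'
#' @param config List as returned by [read_config()]; must carry the keys
#'   `glut1`, `glut2`, `gk` (with their kinetic constants) and
#'   `volume_per_1e5_cells`.
#' @return A [reduced_model_params()] object.
#' @export
params_from_config <- function(config) {
  need <- c("glut1.km", "glut1.vmax_normal", "glut2.km", "glut2.vmax_normal",
            "gk.s_half", "gk.hill_exponent", "gk.vmax_gk",
            "volume_per_1e5_cells")
  for (key in need) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    node <- config
    for (p in parts) {
      if (is.null(node[[p]])) {
        stop("config is missing required key: ", key, call. = FALSE)
      }
      node <- node[[p]]
    }
  }
  e1 <- config$glut1$epsilon; if (is.null(e1)) e1 <- 1
  e2 <- config$glut2$epsilon; if (is.null(e2)) e2 <- 1
  reduced_model_params(
    glut1 = transporter_kinetics("GLUT1", config$glut1$km,
                                 config$glut1$vmax_normal, e1),
    glut2 = transporter_kinetics("GLUT2", config$glut2$km,
                                 config$glut2$vmax_normal, e2),
    gk = gk_kinetics(config$gk$s_half, config$gk$hill_exponent,
                     config$gk$vmax_gk),
    volume_per_1e5_cells = config$volume_per_1e5_cells
  )
}

#' Write a table as annotated TSV
#'
#' Tab-separated output with `#`-prefixed header comments recording the
#' package version and any unit annotations, then a column-name row.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param comments Extra comment lines (units, scenario, seed).
#' @param sep Field separator (`"\t"` or `","`).
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(df, path, comments = character(), sep = "\t") {
  stopifnot(is.data.frame(df))
  header <- paste0("# ", c(paste0("bcglut ", as.character(packageVersion("bcglut"))),
                           comments))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an annotated TSV written by [write_table_tsv()]
#'
#' @param path File path.
#' @param sep Field separator.
#' @return Data frame (comment lines skipped).
#' @export
read_table_tsv <- function(path, sep = "\t") {
  read.delim(path, sep = sep, comment.char = "#",
             stringsAsFactors = FALSE)
}
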