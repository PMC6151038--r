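#' Build a generator configuration from a YAML file
#'
#' Reads a YAML file whose keys mirror the arguments of
#' [generator_config()] (unknown keys are rejected); list values for
#' `object_means` are converted to the framing-by-object matrices the
#' generator expects. A commented template ships with the package:
#' `system.file("extdata", "generator_config_template.yaml",
#' package = "raschval")`.
#'
#' @param path YAML file path.
#' @return a `generator_config`.
#' @export
generator_config_from_yaml <- function(path) {
  stopifnot(file.exists(path))
  raw <- yaml::read_yaml(path)
  known <- names(formals(generator_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0L) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$object_means)) {
    raw$object_means <- lapply(raw$object_means, function(sc) {
      m <- do.call(rbind, lapply(sc, unlist))
      rownames(m) <- names(sc)
      m
    })
  }
  for (nm in c("group_offsets", "carry_over", "person_sd", "dk_rate")) {
    if (!is.null(raw[[nm]]) && is.list(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(generator_config, raw)
}
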