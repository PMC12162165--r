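#' Load an experiment configuration from a YAML file
#'
#' Reads a structured config with optional sections `design`, `protocol`,
#' `params`, `split` and `run` and assembles an [experiment_config()].
#' Unknown keys are rejected so typos fail loudly. See
#' `system.file("cli", "example-config.yaml", package = "specklesense")`
#' for the accepted layout.
#'
#' @param path Path to a YAML file.
#' @return An [experiment_config()].
#' @export
load_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  take <- function(section, builder) {
    args <- cfg[[section]]
    if (is.null(args)) return(builder())
    known <- names(formals(builder))
    bad <- setdiff(names(args), known)
    if (length(bad)) {
      stop("unknown key(s) in config section '", section, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    do.call(builder, args)
  }
  protocol <- take("protocol", recording_protocol)
  design_args <- cfg$design
  if (!is.null(design_args)) {
    design_args <- lapply(design_args, function(v)
      if (is.list(v)) unlist(v) else v)
    design_args$protocol <- NULL  # protocol comes from its own section
    bad <- setdiff(names(design_args),
                   names(formals(speckle_design)))
    if (length(bad)) {
      stop("unknown key(s) in config section 'design': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    design <- do.call(speckle_design,
                      c(design_args, list(protocol = protocol)))
  } else {
    design <- speckle_design(protocol = protocol)
  }
  params <- take("params", gbt_params)
  run <- cfg$run
  fr <- cfg$split
  fractions <- if (is.null(fr)) c(train = 0.8, validation = 0.2)
               else unlist(fr)
  experiment_config(
    design = design, params = params, fractions = fractions,
    seed = if (is.null(run$seed)) 1L else as.integer(run$seed),
    include_control = if (is.null(run$include_control)) TRUE
                      else isTRUE(run$include_control),
    chunk_len = if (is.null(run$chunk_len)) 40 else run$chunk_len)
}
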