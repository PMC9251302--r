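#' Read a model/forcing/thermal configuration file
#'
#' YAML (or JSON) with up to three top-level blocks. `model` holds
#' overrides of the fifteen parameter names used by [nfkb_params()];
#' `forcing` mirrors the arguments of [forcing_protocol()] (`tnf_steps`
#' as a list of `{time, level}` pairs); `thermal` holds `T_ref_K` and an
#' optional `rates` map of per-rate entries `{law: reaction|diffusion|none,
#' S: <number>}`. Unknown keys at any level are an error.
#'
#' @param path file path; `.json` files are parsed as JSON, anything else
#'   as YAML.
#' @return A list with elements `params`, `forcing`, `thermal`.
#' @export
read_model_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known_top <- c("model", "forcing", "thermal")
  bad <- setdiff(names(cfg), known_top)
  if (length(bad)) abort(paste0("unknown config block(s): ",
                                paste(bad, collapse = ", ")))
  params <- do.call(nfkb_params, as.list(cfg$model %||% list()))
  forcing <- parse_forcing_block(cfg$forcing %||% list())
  thermal <- parse_thermal_block(cfg$thermal %||% list())
  list(params = params, forcing = forcing, thermal = thermal)
}

parse_forcing_block <- function(fc) {
  known <- c("tnf_mode", "tnf_base", "tnf_amplitude", "tnf_period",
             "tnf_steps", "temp_mode", "temp_base", "temp_amplitude",
             "temp_frequency")
  bad <- setdiff(names(fc), known)
  if (length(bad)) abort(paste0("unknown forcing key(s): ",
                                paste(bad, collapse = ", ")))
  if (!is.null(fc$tnf_steps)) {
    fc$tnf_steps <- dplyr::bind_rows(lapply(fc$tnf_steps, as_tibble))
  }
  do.call(forcing_protocol, fc)
}

parse_thermal_block <- function(th) {
  bad <- setdiff(names(th), c("T_ref_K", "rates"))
  if (length(bad)) abort(paste0("unknown thermal key(s): ",
                                paste(bad, collapse = ", ")))
  laws <- default_thermal_laws()
  if (!is.null(th$rates)) {
    for (r in names(th$rates)) {
      i <- which(laws$rate == r)
      if (!length(i)) abort(paste0("unknown rate in thermal block: ", r))
      entry <- th$rates[[r]]
      bad <- setdiff(names(entry), c("law", "S"))
      if (length(bad)) abort(paste0("unknown thermal rate key(s): ",
                                    paste(bad, collapse = ", ")))
      if (!is.null(entry$law)) {
        laws$law[i] <- c(reaction = "reaction", diffusion = "diffusion",
                         none = "none")[[entry$law]]
      }
      if (!is.null(entry$S)) laws$S[i] <- entry$S
    }
  }
  thermal_config(T_ref_K = th$T_ref_K %||% 310.15, laws = laws)
}

#' Read downstream gene specifications from YAML
#'
#' The file lists one block per gene with the [gene_spec()] fields
#' (`gamma`, `delta`, `Gamma`, `Delta`, `h`, `K`).
#'
#' @param path YAML file path.
#' @return A named list of `gene_spec` objects.
#' @export
read_gene_specs <- function(path) {
  cfg <- yaml::read_yaml(path)
  specs <- lapply(names(cfg), function(nm) {
    do.call(gene_spec, c(list(name = nm), cfg[[nm]]))
  })
  setNames(specs, names(cfg))
}
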