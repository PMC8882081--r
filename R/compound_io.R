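#' Read and write compound records as YAML
#'
#' Compound records are stored as annotated YAML key-value files; the schema
#' mirrors the fields of [compound_record()] (schema_version 1). The
#' round-trip `save_compound()` then `load_compound()` is lossless on every
#' field. Validation failures name the offending field.
#'
#' @param path Path to a `.yaml` compound file.
#' @return A [compound_record()].
#' @seealso [pbpk_example_compound()] for the records shipped with the
#'   package.
#' @export
load_compound <- function(path) {
  if (!file.exists(path)) stop(sprintf("compound file not found: %s", path))
  y <- yaml::read_yaml(path)
  required <- c("name", "molecular_weight", "logP", "fu_plasma", "fa", "ka")
  miss <- setdiff(required, names(y))
  if (length(miss)) {
    stop(sprintf("compound file '%s' is missing required field(s): %s",
                 basename(path), paste(miss, collapse = ", ")))
  }
  ints <- lapply(y$interaction_set, function(ip) {
    do.call(interaction_param, ip)
  })
  cy <- y$cyp_clint
  if (!is.null(cy)) cy <- unlist(cy)
  hu <- y$hepatic_uptake
  if (!is.null(hu)) hu <- unlist(hu)
  rg <- y$retrograde
  if (!is.null(rg)) rg$fm <- unlist(rg$fm)
  compound_record(
    name = y$name,
    molecular_weight = y$molecular_weight,
    logP = y$logP,
    pKa_list = if (is.null(y$pKa_list)) numeric(0) else unlist(y$pKa_list),
    compound_type = if (is.null(y$compound_type)) "neutral" else y$compound_type,
    blood_plasma_ratio = if (is.null(y$blood_plasma_ratio)) 1 else y$blood_plasma_ratio,
    fu_plasma = y$fu_plasma,
    fa = y$fa,
    ka = y$ka,
    fu_gut = if (is.null(y$fu_gut)) 1 else y$fu_gut,
    gut_cyp3a4 = isTRUE(y$gut_cyp3a4),
    clu_int_gut = y$clu_int_gut,
    kp_scalar = if (is.null(y$kp_scalar)) 1 else y$kp_scalar,
    vss_target = y$vss_target,
    clpo = y$clpo,
    retrograde = rg,
    cyp_clint = cy,
    additional_hlm_clint = y$additional_hlm_clint,
    renal_cl = if (is.null(y$renal_cl)) 0 else y$renal_cl,
    kidney_model = y$kidney_model,
    hepatic_uptake = hu,
    interaction_set = ints
  )
}

#' @rdname load_compound
#' @param record A [compound_record()].
#' @export
save_compound <- function(record, path) {
  stopifnot(inherits(record, "compound_record"))
  y <- unclass(record)
  y$interaction_set <- lapply(record$interaction_set, function(ip) {
    out <- unclass(ip)
    out[!vapply(out, is.null, logical(1))]
  })
  y$cyp_clint <- as.list(record$cyp_clint)
  y$hepatic_uptake <- as.list(record$hepatic_uptake)
  if (!is.null(y$retrograde)) y$retrograde$fm <- as.list(record$retrograde$fm)
  y <- y[!vapply(y, function(v) is.null(v) || (is.list(v) && length(v) == 0 && !is.numeric(v)), logical(1))]
  if (length(record$pKa_list) == 0) y$pKa_list <- NULL
  y <- c(list(schema_version = 1L), y)
  yaml::write_yaml(y, path, precision = 15L)
  invisible(path)
}

#' Load a compound record shipped with the package
#'
#' @param name One of `"dasatinib"`, `"metformin"`, `"pravastatin"`,
#'   `"rosuvastatin"`, `"simvastatin"`, `"ketoconazole"`, `"rifampin"`.
#' @return A [compound_record()].
#' @examples
#' das <- pbpk_example_compound("dasatinib")
#' das$fu_plasma # 0.04
#' @export
pbpk_example_compound <- function(name) {
  path <- system.file("extdata", "compounds", paste0(name, ".yaml"),
                      package = "pbpkddi")
  if (path == "") {
    stop(sprintf("no shipped compound record named '%s'", name))
  }
  load_compound(path)
}
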