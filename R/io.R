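# Serialization: networks and flux configurations as structured JSON
# documents, tidy tables as CSV. Everything is schema-validated on load via
# the classes' validity methods.

#' Write / read a carbon network as JSON
#'
#' @param net a [CarbonNetwork-class]
#' @param path file path
#' @return `readCarbonNetwork` returns a validated `CarbonNetwork`;
#'   `writeCarbonNetwork` returns `path` invisibly
#' @export
writeCarbonNetwork <- function(net, path) {
  doc <- list(
    metabolites = net@metabolites,
    reactions = lapply(unname(net@reactions), function(r)
      list(name = r$name, inputs = r$inputs, outputs = r$outputs,
           map = r$map)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCarbonNetwork
#' @export
readCarbonNetwork <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  met <- as.data.frame(doc$metabolites, stringsAsFactors = FALSE)
  met$n_carbons <- as.integer(met$n_carbons)
  rx <- lapply(seq_len(nrow(doc$reactions)), function(i) {
    r <- doc$reactions[i, ]
    map <- as.data.frame(r$map[[1]], stringsAsFactors = FALSE)
    map$sub_carbon <- as.integer(map$sub_carbon)
    map$prod_carbon <- as.integer(map$prod_carbon)
    list(name = r$name, inputs = unlist(r$inputs),
         outputs = unlist(r$outputs), map = map)
  })
  names(rx) <- vapply(rx, `[[`, "", "name")
  net <- new("CarbonNetwork", metabolites = met, reactions = rx)
  validObject(net)
  net
}

#' Write / read a flux configuration as JSON
#'
#' @param cfg a [FluxConfig-class]
#' @param path file path
#' @return `readFluxConfig` returns a validated `FluxConfig`;
#'   `writeFluxConfig` returns `path` invisibly
#' @export
writeFluxConfig <- function(cfg, path) {
  doc <- list(fractions = lapply(cfg@fractions, as.list),
              tracer_purity = cfg@tracerPurity,
              co2_labeled_fraction = cfg@co2LabeledFraction)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFluxConfig
#' @export
readFluxConfig <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  fractions <- lapply(doc$fractions, function(f) unlist(f))
  fluxConfig(fractions, tracerPurity = doc$tracer_purity,
             co2LabeledFraction = doc$co2_labeled_fraction)
}

#' Write / read a tidy MID table as CSV
#'
#' @param table a tidy MID data.frame
#' @param path file path
#' @param net optional network for schema validation on read
#' @return `readMidTable` returns the validated data.frame
#' @export
writeMidTable <- function(table, path) {
  validateMidTable(table)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMidTable
#' @export
readMidTable <- function(path, net = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validateMidTable(tab, net = net)
  tab
}
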