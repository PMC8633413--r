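#' Read a marker genotype table
#'
#' Expects a CSV (or TSV for `.tsv` files) with columns `marker_id`,
#' `segregation` (optionally `chromosome`, `position`) followed by one column
#' per individual with integer genotype codes: 0/1 for testcross markers
#' (segregating 1:1), 0/1/2 for intercross markers (1:2:1); NA allowed.
#'
#' @param path file path.
#' @return A `cri_geno` object.
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("genotype file not found: ", path,
                               call. = FALSE)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("marker_id", "segregation")
  if (!all(need %in% names(df)))
    stop("genotype table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- which(!df$segregation %in% c("testcross", "intercross"))
  if (length(bad))
    stop("unknown segregation label(s) at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         "; allowed: testcross, intercross", call. = FALSE)
  meta_cols <- intersect(c("marker_id", "chromosome", "position",
                           "segregation"), names(df))
  id_cols <- setdiff(names(df), meta_cols)
  if (!length(id_cols)) stop("no individual columns found", call. = FALSE)
  codes <- as.matrix(df[id_cols])
  if (!is.numeric(codes)) stop("genotype codes must be numeric",
                               call. = FALSE)
  maxcode <- ifelse(df$segregation == "testcross", 1L, 2L)
  bad <- which(apply(codes, 1, function(r) any(r < 0 | r > 2, na.rm = TRUE)) |
                 apply(codes > maxcode, 1, any) %in% TRUE)
  bad <- unique(c(bad, which(rowSums(codes > maxcode, na.rm = TRUE) > 0)))
  if (length(bad))
    stop("genotype codes out of range for segregation type at data row(s) ",
         paste(utils::head(sort(bad), 5), collapse = ", "), call. = FALSE)
  info <- data.frame(marker_id = as.character(df$marker_id),
                     chromosome = if ("chromosome" %in% names(df))
                       as.character(df$chromosome) else NA_character_,
                     position = if ("position" %in% names(df))
                       df$position else seq_len(nrow(df)),
                     segregation = df$segregation, stringsAsFactors = FALSE)
  structure(list(info = info, codes = unname(codes), ids = id_cols),
            class = "cri_geno")
}

#' Write a marker genotype table
#'
#' @param geno a `cri_geno` object.
#' @param path output CSV (or `.tsv`) path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  codes <- as.data.frame(geno$codes)
  names(codes) <- geno$ids
  out <- cbind(geno$info, codes)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format phenotype table
#'
#' Expects a CSV with columns `individual`, `trait` (`height` or
#' `diameter`), `time`, `value`. The design must be balanced: every
#' individual measured for both traits at every time point.
#'
#' @param path file path.
#' @return A [cri_pheno()] object.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual", "trait", "time", "value")
  if (!all(need %in% names(df)))
    stop("phenotype table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- which(!df$trait %in% c("height", "diameter"))
  if (length(bad))
    stop("unknown trait label at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         "; allowed: height, diameter", call. = FALSE)
  times <- sort(unique(df$time))
  ids <- unique(df$individual)
  cnt <- table(df$individual, df$trait)
  if (any(cnt != length(times)))
    stop("unbalanced design: every individual needs both traits at all ",
         length(times), " time points", call. = FALSE)
  grab <- function(tr) {
    sub <- df[df$trait == tr, ]
    m <- matrix(NA_real_, length(ids), length(times),
                dimnames = list(ids, times))
    m[cbind(match(sub$individual, ids), match(sub$time, times))] <- sub$value
    if (anyNA(m)) stop("duplicate or missing ", tr, " measurements",
                       call. = FALSE)
    m
  }
  cri_pheno(grab("height"), grab("diameter"), times, ids = ids)
}

#' Write a long-format phenotype table
#'
#' @param pheno a [cri_pheno()] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  T <- length(pheno$times)
  n <- nrow(pheno$height)
  out <- data.frame(
    individual = rep(pheno$ids, times = 2 * T),
    trait = rep(c("height", "diameter"), each = n * T),
    time = rep(rep(pheno$times, each = n), times = 2),
    value = c(as.vector(pheno$height), as.vector(pheno$diameter)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write scan results
#'
#' @param scan a `cri_scan`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(scan, path) {
  utils::write.table(scan$results, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write effect curves as a wide CSV
#'
#' @param ec an `effect_curve_set`.
#' @param path output CSV path (marker x time; height block then diameter
#'   block).
#' @return `path`, invisibly.
#' @export
write_effect_curves <- function(ec, path) {
  out <- data.frame(marker_id = ec$ids, qtl = ec$qtl,
                    ec$g1, ec$g2, check.names = FALSE)
  names(out) <- c("marker_id", "qtl",
                  paste0("height_t", ec$times),
                  paste0("diameter_t", ec$times))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read effect curves from a wide CSV
#'
#' @param path file written by [write_effect_curves()].
#' @param times observation times (reconstructed from the header when NULL).
#' @return An `effect_curve_set`.
#' @export
read_effect_curves <- function(path, times = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  hcols <- grep("^height_t", names(df))
  dcols <- grep("^diameter_t", names(df))
  if (is.null(times))
    times <- as.numeric(sub("^height_t", "", names(df)[hcols]))
  structure(list(times = times,
                 g1 = as.matrix(df[hcols]), g2 = as.matrix(df[dcols]),
                 independent_g1 = NULL, independent_g2 = NULL,
                 ids = df$marker_id,
                 qtl = if ("qtl" %in% names(df)) df$qtl
                   else rep(FALSE, nrow(df))),
            class = "effect_curve_set")
}

#' Write a network edge list (CSV, optionally GraphML)
#'
#' @param net an `epistatic_network`.
#' @param path output CSV path.
#' @param graphml optional GraphML output path (written via igraph).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, graphml = NULL) {
  ed <- net$edges
  if (nrow(ed)) {
    ed$trait <- net$trait; ed$variant <- net$variant; ed$layer <- net$layer
  } else {
    ed <- data.frame(source = character(0), target = character(0),
                     sign = character(0), weight = numeric(0),
                     trait = character(0), variant = character(0),
                     layer = character(0))
  }
  utils::write.csv(ed, path, row.names = FALSE, quote = FALSE)
  if (!is.null(graphml))
    igraph::write_graph(as_igraph(net), graphml, format = "graphml")
  invisible(path)
}

pipeline_config_defaults <- function() {
  list(seed = 1,
       sim = list(n = 66, p = 100, prop_testcross = 0.6, causal_index = 1,
                  effect_size = 0.10, H2 = 0.05, times = 1:14),
       mapping = list(alpha = 0.05, step = 0.05, subtests = TRUE),
       clustering = list(L_range = 1:6, order = 4, criterion = "BIC"),
       network = list(order_smooth = 4, order_ode = 3, n_dense = 100,
                      selector = "cv", max_in_degree = 8),
       power = list(replicates = 50, conditions = list(list(n = 66, H2 = 0.05))))
}

#' Read and validate a pipeline configuration
#'
#' Accepts YAML or JSON. Unknown keys (at the top level or within a stage
#' block) are rejected by name; omitted keys take package defaults.
#'
#' @param path config file (`.yaml`/`.yml`/`.json`).
#' @return Named list of class `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  # YAML 1.1 parses a bare `n:` key as boolean FALSE; map it back
  fix_n <- function(x) {
    if (is.list(x)) names(x)[names(x) == "FALSE"] <- "n"
    x
  }
  cfg <- fix_n(lapply(cfg, fix_n))
  defaults <- pipeline_config_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (blk in names(cfg)) {
    if (is.list(defaults[[blk]]) && is.list(cfg[[blk]])) {
      bad <- setdiff(names(cfg[[blk]]), names(defaults[[blk]]))
      if (length(bad))
        stop("unknown config key(s) in '", blk, "': ",
             paste(bad, collapse = ", "), call. = FALSE)
      defaults[[blk]][names(cfg[[blk]])] <- cfg[[blk]]
    } else if (!is.null(cfg[[blk]])) {
      defaults[[blk]] <- cfg[[blk]]
    }
  }
  structure(defaults, class = "pipeline_config")
}

#' Write a pipeline configuration
#'
#' @param config a `pipeline_config` (or plain list).
#' @param path output path; `.json` selects JSON, anything else YAML.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  config <- unclass(config)
  if (grepl("\\.json$", path))
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else yaml::write_yaml(config, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration snapshot, package version, timestamps, emitted
#' files and accumulated warnings of a pipeline stage, as JSON.
#'
#' @param path output JSON path.
#' @param config the configuration used.
#' @param outputs named character vector/list of emitted files.
#' @param warnings character vector of surfaced warnings.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, config, outputs, warnings = character(0)) {
  man <- list(package = "crinet",
              version = as.character(utils::packageVersion("crinet")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              config = unclass(config),
              outputs = as.list(outputs),
              warnings = as.list(warnings))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(man)
}
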