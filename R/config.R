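#' Default pipeline configuration
#'
#' Collects every tunable threshold of the survey pipeline in one list.
#' Defaults follow the published conventions for this kind of family survey:
#' a gene is expressed at RPKM > 1; a DEG is called at fold change > 2 (up)
#' or < 0.5 (down); orthologs require E-value <= 1e-40 and >= 70% similarity;
#' tandem arrays allow at most 3 intervening genes; global/local alignments
#' use gap open 10 and gap extension 0.2 on BLOSUM62.
#'
#' @return a named list of class `genefam_config`
#' @export
default_config <- function() {
  cfg <- list(
    profile_threshold_frac = 0.6,  # fraction of consensus self-score
    rpkm_expressed = 1,
    fc_up = 2,
    fc_down = 0.5,
    evalue_max = 1e-40,
    min_similarity = 0.70,
    max_intervening = 3L,
    gap_open = 10,
    gap_extend = 0.2,
    substitution_matrix = "BLOSUM62",
    subgroup_ceiling = 0.75,       # tree path-length cutoff for UNASSIGNED
    fold_epsilon = 0.01,           # RPKM zero guard for fold changes
    bootstrap_reps = 100L,
    seed = 1L
  )
  class(cfg) <- c("genefam_config", "list")
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' @param cfg a list as produced by [default_config()] or [read_config()]
#' @return `cfg`, invisibly classed, after checking invariants
#' @export
validate_config <- function(cfg) {
  num <- c("profile_threshold_frac", "rpkm_expressed", "fc_up", "fc_down",
           "evalue_max", "min_similarity", "gap_open", "gap_extend",
           "subgroup_ceiling", "fold_epsilon")
  for (k in num) {
    v <- cfg[[k]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v) ||
        v <= 0)
      stop_genefam("config field '", k, "' must be a positive number")
  }
  if (!(cfg$fc_down < 1 && 1 < cfg$fc_up))
    stop_genefam("config requires fc_down < 1 < fc_up")
  if (cfg$max_intervening < 0) stop_genefam("max_intervening must be >= 0")
  if (cfg$bootstrap_reps < 1) stop_genefam("bootstrap_reps must be >= 1")
  class(cfg) <- c("genefam_config", "list")
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Fields absent from the file keep their [default_config()] values.
#'
#' @param path path to a YAML file
#' @return a validated `genefam_config` list
#' @export
read_config <- function(path) {
  cfg <- default_config()
  user <- yaml::read_yaml(path)
  for (k in names(user)) cfg[[k]] <- user[[k]]
  validate_config(cfg)
}
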