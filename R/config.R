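#' Read / write a model + design configuration
#'
#' The native configuration is a structured text file (YAML or JSON by
#' extension) with keys `regions`, `inputs` (name, onsets, durations,
#' optional amplitudes), `A`/`C` (and optional per-input `B`) each with
#' `mask` and `values`, plus `tr`, `n_slices`, `n_volumes` and optional
#' `snr` and `seed`.  The schema ships in
#' `system.file("extdata", "config-schema.md", package = "dcmprofile")`.
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`).
#' @return `read_dcm_config()`: list with `model` ([dcm_model()]),
#'   `design` ([design_spec()]), `snr`, `seed`, `name`.
#' @export
read_dcm_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("unsupported config extension: ", ext))
  .config_to_objects(cfg)
}

.num_matrix <- function(x, m, n) {
  if (is.list(x)) x <- do.call(rbind, lapply(x, as.numeric))
  x <- as.matrix(x); storage.mode(x) <- "double"
  if (!identical(dim(x), c(m, n)))
    stop(sprintf("config matrix has dimensions %d x %d, expected %d x %d",
                 nrow(x), ncol(x), m, n))
  x
}

.config_to_objects <- function(cfg) {
  for (k in c("regions", "inputs", "A", "C", "tr", "n_slices", "n_volumes"))
    if (is.null(cfg[[k]])) stop("config is missing the required key '", k, "'")
  regions <- as.character(cfg$regions)
  m <- length(regions)
  inputs <- cfg$inputs
  if (is.data.frame(inputs)) inputs <- split(inputs, seq_len(nrow(inputs)))
  input_names <- vapply(inputs, function(i) as.character(i$name), "")
  ni <- length(input_names)

  a <- cfg$A; cc <- cfg$C
  b_masks <- b_values <- NULL
  if (!is.null(cfg$B)) {
    b_masks <- rep(list(NULL), ni); b_values <- rep(list(NULL), ni)
    for (nm in names(cfg$B)) {
      i <- match(nm, input_names)
      if (is.na(i)) stop("config B refers to unknown input '", nm, "'")
      b_masks[[i]] <- .num_matrix(cfg$B[[nm]]$mask, m, m)
      b_values[[i]] <- .num_matrix(cfg$B[[nm]]$values, m, m)
    }
  }
  model <- dcm_model(
    a_mask = .num_matrix(a$mask, m, m), a_values = .num_matrix(a$values, m, m),
    c_mask = .num_matrix(cc$mask, m, ni),
    c_values = .num_matrix(cc$values, m, ni),
    b_masks = b_masks, b_values = b_values,
    region_names = regions, input_names = input_names)

  stimuli <- lapply(inputs, function(i)
    data.frame(onset = as.numeric(unlist(i$onsets)),
               duration = as.numeric(unlist(i$durations)),
               amplitude = if (is.null(i$amplitudes)) 1
               else as.numeric(unlist(i$amplitudes))))
  names(stimuli) <- input_names
  design <- design_spec(cfg$tr, cfg$n_slices, cfg$n_volumes, stimuli)
  list(model = model, design = design,
       snr = if (is.null(cfg$snr)) NULL else cfg$snr,
       seed = if (is.null(cfg$seed)) NULL else as.integer(cfg$seed),
       name = cfg$name)
}

#' @rdname read_dcm_config
#' @param model,design,snr,seed,name the objects to serialize.
#' @export
write_dcm_config <- function(path, model, design, snr = NULL, seed = NULL,
                             name = NULL) {
  cfg <- c(if (!is.null(name)) list(name = name),
           list(regions = model$region_names),
           list(inputs = lapply(seq_along(model$input_names), function(i) {
             st <- design$stimuli[[model$input_names[i]]]
             if (is.null(st)) st <- data.frame(onset = numeric(0),
                                               duration = numeric(0),
                                               amplitude = numeric(0))
             list(name = model$input_names[i],
                  onsets = as.numeric(st$onset),
                  durations = as.numeric(st$duration),
                  amplitudes = as.numeric(st$amplitude))
           })),
           list(A = list(mask = .mat_rows(model$a_mask),
                         values = .mat_rows(model$a_values)),
                C = list(mask = .mat_rows(model$c_mask),
                         values = .mat_rows(model$c_values))))
  bs <- which(vapply(model$b_masks, sum, 0) > 0)
  if (length(bs)) {
    cfg$B <- setNames(lapply(bs, function(i)
      list(mask = .mat_rows(model$b_masks[[i]]),
           values = .mat_rows(model$b_values[[i]]))),
      model$input_names[bs])
  }
  cfg <- c(cfg, list(tr = design$tr, n_slices = design$n_slices,
                     n_volumes = design$n_volumes))
  if (!is.null(snr)) cfg$snr <- snr
  if (!is.null(seed)) cfg$seed <- seed

  ext <- tolower(tools::file_ext(path))
  switch(ext,
         yaml = , yml = yaml::write_yaml(cfg, path, precision = 12),
         json = jsonlite::write_json(cfg, path, digits = NA,
                                     auto_unbox = TRUE, pretty = TRUE),
         stop("unsupported config extension: ", ext))
  invisible(path)
}

.mat_rows <- function(x) lapply(seq_len(nrow(x)), function(r) as.numeric(x[r, ]))

.design_to_list <- function(design) {
  list(tr = design$tr, n_slices = design$n_slices,
       n_volumes = design$n_volumes, sample_offset = design$sample_offset,
       stimuli = lapply(design$stimuli, function(st) as.list(st)))
}

.design_from_list <- function(x) {
  stimuli <- lapply(x$stimuli, function(st)
    data.frame(onset = as.numeric(unlist(st$onset)),
               duration = as.numeric(unlist(st$duration)),
               amplitude = if (is.null(st$amplitude)) 1
               else as.numeric(unlist(st$amplitude))))
  design_spec(x$tr, x$n_slices, x$n_volumes, stimuli,
              if (is.null(x$sample_offset)) 0L else x$sample_offset)
}

#' Load a bundled network fixture
#'
#' Two three-region visual-attention networks (V1, V5, SPC) are bundled:
#' \describe{
#'   \item{`"forward"`}{V1 and V5 bidirectionally connected, V5 and SPC
#'     bidirectionally connected, three self-connections (7 `A`
#'     parameters); one driving input Photic into V1; two modulatory
#'     inputs, Motion and Attention, both on the forward connection
#'     V1 -> V5.  10 free parameters.}
#'   \item{`"backward"`}{same `A` and `C` structure; Motion modulates
#'     V1 -> V5 and Attention the backward connection SPC -> V5.}
#' }
#' Parameter values are documented plausible defaults (inhibitory
#' self-connections -0.5 Hz, inter-regional +0.3 Hz, driving input 0.8,
#' modulations 0.4), versioned in the fixture config files; the stimulus
#' train is rule-generated (alternating 32.2 s epochs, onset spacing
#' 64.4 s per input).  The default design is TR 3.22 s, 32 slices,
#' 360 volumes (19.32 min session), SNR 10.
#'
#' @param name `"forward"` or `"backward"`.
#' @return List with `name`, `model`, `params`, `design`, `snr`, `seed`.
#' @export
load_fixture <- function(name) {
  available <- c("forward", "backward")
  if (!is.character(name) || length(name) != 1 || !(name %in% available))
    stop(sprintf("unknown fixture '%s'; available fixtures: %s",
                 as.character(name)[1], paste(available, collapse = ", ")))
  path <- system.file("extdata", "fixtures", paste0(name, ".yaml"),
                      package = "dcmprofile", mustWork = TRUE)
  cfg <- read_dcm_config(path)
  list(name = name, model = cfg$model, params = pack_params(cfg$model),
       design = cfg$design, snr = cfg$snr, seed = cfg$seed)
}
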