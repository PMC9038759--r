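# Pipeline configuration: YAML with full defaulting and strict
# unknown-key rejection (a silently ignored typo corrupts experiments).

default_config <- function() {
  list(
    seed = 1L,
    deterministic = TRUE,
    stages = c("simulate", "fit", "retrieve", "evaluate"),
    simulate = list(kind = "shepp_logan", size = 256L, pad_px = 32L,
                    theta_pattern = "phantom", a0_ref = 70000,
                    a1_ref = 30000, M = 8L, eta_range = 0.05,
                    deriv_scale = 1.0, noisy = TRUE),
    fit = list(darkfield_form = "visibility"),
    mask = list(enabled = TRUE, t_transmission = 0.95, t_dpci = 0.1,
                t_darkfield = 0.8, opening_radius = 0L),
    retrieve = list(method = "integrate",
                    wf = list(wavelet = "db4", levels = 4L, sigma = 2.0),
                    admm = list(lambda1 = 0.001, lambda2 = 1, c = 1,
                                rho = 1, max_iter = 200L, tol = 1e-5)),
    train = list(epochs = 10L, iterations_per_epoch = 50L, lr0 = 1e-4,
                 lambda1 = 0.001, lambda2 = 1, patch_size = 48L,
                 patches_per_iteration = 16L, subset_min = NA,
                 subset_max = NA, flip_augment = TRUE),
    evaluate = list(enabled = TRUE)
  )
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user) || !is.list(defaults)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)),
                collapse = ", "))
  for (k in names(user))
    defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                  paste0(path, ".", k))
  defaults
}

#' Read and validate a pipeline configuration file
#'
#' Reads a YAML configuration, fills every omitted key from the package
#' defaults and rejects unknown keys with an error naming them.
#'
#' @param path YAML file; `NULL` returns the full default configuration.
#' @return validated configuration list.
#' @seealso [run_pipeline()]
#' @export
read_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  cfg <- merge_config(default_config(), user)
  known_stages <- c("simulate", "fit", "retrieve", "train", "predict",
                    "evaluate")
  bad <- setdiff(cfg$stages, known_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  cfg
}
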