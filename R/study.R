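#' Build the evaluation session plan
#'
#' Enumerates the measurement tasks of the evaluation protocol: the
#' calibration phantom contributes six tasks (horizontal and vertical
#' diameters of the 4, 6 and 10 mm low-scatter cysts) and each patient
#' dataset contributes five standard echocardiographic measurements with
#' their views and cardiac phases — aortic valve hingepoint and left
#' atrial dimension (parasternal long axis, systole), left ventricular
#' end-diastolic dimension (short axis, diastole), left ventricular
#' end-systolic dimension and aortic end-systolic dimension (short axis,
#' end systole, mitral valve closed). With the defaults (4 patients, the
#' phantom) the plan holds 26 tasks per participant.
#'
#' @param n_patients Number of patient datasets (default 4).
#' @param include_phantom Include the six phantom tasks (default TRUE).
#' @return A tibble (class `session_plan`) with columns `dataset`,
#'   `dataset_type` ("phantom"/"patient"), `view`, `phase`, `measurement`.
#' @export
build_session_plan <- function(n_patients = 4, include_phantom = TRUE) {
  stopifnot(n_patients >= 0)
  phantom <- if (include_phantom) {
    tidyr::expand_grid(size = c(4, 6, 10), axis = c("V", "H")) |>
      dplyr::mutate(
        dataset = "phantom",
        dataset_type = "phantom",
        view = NA_character_,
        phase = NA_character_,
        measurement = sprintf("low scatter cyst %g mm %s diameter", .data$size, .data$axis)
      ) |>
      dplyr::select("dataset", "dataset_type", "view", "phase", "measurement")
  } else NULL
  patient_tasks <- tibble::tribble(
    ~view,                        ~phase,                   ~measurement,
    "parasternal long axis view", "systole",                "aortic valve hingepoint",
    "parasternal long axis view", "systole",                "left atrial dimension",
    "short axis view",            "diastolic",              "left ventricular end diastolic dimension",
    "short axis view",            "end systolic MV closed", "left ventricular end systolic dimension",
    "short axis view",            "end systolic MV closed", "aortic end systolic dimension"
  )
  patients <- if (n_patients > 0) {
    tidyr::expand_grid(dataset = sprintf("patient%d", seq_len(n_patients)),
                       patient_tasks) |>
      dplyr::mutate(dataset_type = "patient") |>
      dplyr::select("dataset", "dataset_type", "view", "phase", "measurement")
  } else NULL
  plan <- dplyr::bind_rows(phantom, patients)
  class(plan) <- c("session_plan", class(plan))
  plan
}

#' Tool measurement models
#'
#' A tool model describes how a measurement tool corrupts a true length:
#' each endpoint of the caliper is perturbed by an independent isotropic
#' Gaussian of the tool's `sigma_mm` (placement error), the perturbed
#' chord length gets the tool's additive `bias_mm`, and the displayed
#' value is quantized to the tool's `precision_mm`.
#'
#' `default_tools()` returns the three tools of the comparison study with
#' their published display precisions (0.1 mm, 1 mm, 0.1 mm). The sigmas
#' are free parameters calibrated so the induced length SDs
#' (about `sqrt(2) * sigma`) fall in the range reported for the phantom
#' sizing study (0.2–1.9 mm); biases default to 0.
#'
#' @param name Tool names.
#' @param sigma_mm Per-endpoint isotropic Gaussian SD, mm (>= 0).
#' @param precision_mm Display quantization, mm (> 0).
#' @param bias_mm Additive length bias, mm.
#' @return A tibble (class `tool_models`) with one row per tool.
#' @export
tool_models <- function(name, sigma_mm, precision_mm, bias_mm = 0) {
  stopifnot(all(sigma_mm >= 0), all(precision_mm > 0))
  out <- tibble::tibble(name = as.character(name),
                        sigma_mm = as.numeric(sigma_mm),
                        precision_mm = as.numeric(precision_mm),
                        bias_mm = as.numeric(bias_mm))
  class(out) <- c("tool_models", class(out))
  out
}

#' @rdname tool_models
#' @export
default_tools <- function() {
  tool_models(
    name = c("QLAB", "Tomtec", "VR"),
    sigma_mm = c(0.25, 0.45, 0.70),
    precision_mm = c(0.1, 1.0, 0.1),
    bias_mm = 0
  )
}

#' Default true lengths for a session plan
#'
#' Assigns a plausible ground-truth length to every task of a plan:
#' phantom tasks take their insert's true diameter; patient tasks take
#' typical values of the corresponding clinical dimensions with a small
#' fixed per-dataset offset, so the overall scale of the simulated study
#' (values roughly 4–50 mm, patient mean near 29 mm) matches a paediatric
#' echocardiographic measurement session.
#'
#' @param plan A [build_session_plan()] tibble.
#' @return The plan with an added `truth_mm` column.
#' @export
default_truth <- function(plan) {
  base <- c(
    "aortic valve hingepoint" = 18,
    "left atrial dimension" = 35,
    "left ventricular end diastolic dimension" = 45,
    "left ventricular end systolic dimension" = 30,
    "aortic end systolic dimension" = 20
  )
  plan |>
    dplyr::mutate(
      patient_idx = suppressWarnings(as.integer(sub("patient", "", .data$dataset))),
      truth_mm = dplyr::if_else(
        .data$dataset_type == "phantom",
        suppressWarnings(as.numeric(sub("^low scatter cyst ([0-9.]+) mm.*$", "\\1",
                                        .data$measurement))),
        unname(base[.data$measurement]) + 2 * (.data$patient_idx %% 4) - 3
      )
    ) |>
    dplyr::select(-"patient_idx")
}

#' Simulate observer measurement sessions
#'
#' Draws one measurement record per (user, tool, task): a segment of the
#' task's true length has both endpoints perturbed by the tool's isotropic
#' endpoint noise, the perturbed chord length gets the tool's bias, is
#' clipped at zero (with a warning) and quantized at the tool's display
#' precision. Optionally a stated number of task instances are marked
#' invalid ("incorrectly recorded"): `omit_n` distinct (user, dataset,
#' measurement) combinations are drawn without replacement and within each
#' the record of one tool (`omit_tool`, or a random tool) is invalidated.
#' Deterministic given `seed`.
#'
#' @param plan A [build_session_plan()] tibble with a `truth_mm` column
#'   (see [default_truth()]), or supply `truth` separately.
#' @param users Character vector of user ids (default 5 users).
#' @param tools A [tool_models()] tibble.
#' @param seed Integer RNG seed.
#' @param truth Optional tibble (`dataset`, `measurement`, `truth_mm`)
#'   joined onto the plan.
#' @param omit_n Number of task instances to invalidate (default 0).
#' @param omit_tool Tool whose record is invalidated in each chosen
#'   instance; `NULL` picks a tool at random per instance.
#' @return A tibble (class `measurement_records`) with columns `user`,
#'   `tool`, `dataset`, `measurement`, `value_mm`, `valid`.
#' @export
simulate_observer <- function(plan, users = sprintf("user%d", 1:5),
                              tools = default_tools(), seed = 1L,
                              truth = NULL, omit_n = 0L, omit_tool = NULL) {
  if (!is.null(truth)) {
    plan <- dplyr::left_join(plan, truth, by = c("dataset", "measurement"))
  }
  if (!"truth_mm" %in% names(plan) || anyNA(plan$truth_mm)) {
    rlang::abort("truth_mm must be defined for every task",
                 class = "caliper3d_configuration_error")
  }
  stopifnot(omit_n >= 0)
  tasks <- dplyr::as_tibble(plan)[, c("dataset", "measurement", "truth_mm")]
  grid <- tidyr::expand_grid(user = users, tool = tools$name, tasks) |>
    dplyr::left_join(dplyr::as_tibble(tools), by = c("tool" = "name"))
  withr::with_seed(seed, {
    n <- nrow(grid)
    # endpoints a = 0, b = (L,0,0), each perturbed by N(0, sigma^2 I3)
    ea <- matrix(stats::rnorm(3 * n), ncol = 3) * grid$sigma_mm
    eb <- matrix(stats::rnorm(3 * n), ncol = 3) * grid$sigma_mm
    delta <- cbind(grid$truth_mm + eb[, 1] - ea[, 1],
                   eb[, 2] - ea[, 2],
                   eb[, 3] - ea[, 3])
    len <- sqrt(rowSums(delta^2)) + grid$bias_mm
    if (any(len < 0)) {
      rlang::warn(sprintf("%d simulated length(s) below 0 clipped at 0",
                          sum(len < 0)))
      len <- pmax(len, 0)
    }
    grid$value_mm <- quantize(len, grid$precision_mm)
    grid$valid <- TRUE
    if (omit_n > 0) {
      inst <- dplyr::distinct(grid, .data$user, .data$dataset, .data$measurement)
      if (omit_n > nrow(inst)) {
        rlang::abort("omit_n exceeds the number of task instances",
                     class = "caliper3d_configuration_error")
      }
      pick <- inst[sample.int(nrow(inst), omit_n), ]
      pick$bad_tool <- if (is.null(omit_tool)) {
        sample(tools$name, omit_n, replace = TRUE)
      } else {
        if (!omit_tool %in% tools$name) {
          rlang::abort(sprintf("unknown omit_tool '%s'", omit_tool),
                       class = "caliper3d_configuration_error")
        }
        rep(omit_tool, omit_n)
      }
      grid <- grid |>
        dplyr::left_join(pick, by = c("user", "dataset", "measurement")) |>
        dplyr::mutate(valid = is.na(.data$bad_tool) | .data$tool != .data$bad_tool) |>
        dplyr::select(-"bad_tool")
    }
  })
  out <- grid[, c("user", "tool", "dataset", "measurement", "value_mm", "valid")]
  class(out) <- c("measurement_records", class(out))
  out
}

#' Read and write measurement record tables
#'
#' Records travel as a tab-delimited table with columns `user`, `tool`,
#' `dataset`, `measurement`, `value_mm`, `valid` — the interchange format
#' between the simulator (or a real study) and the evaluation statistics.
#'
#' @param records A records tibble.
#' @param path File path (TSV).
#' @return `records_read()` returns the records tibble;
#'   `records_write()` returns `path`, invisibly.
#' @export
records_write <- function(records, path) {
  readr::write_tsv(records, path)
  invisible(path)
}

#' @rdname records_write
#' @export
records_read <- function(path) {
  out <- readr::read_tsv(
    path,
    col_types = readr::cols(
      user = readr::col_character(),
      tool = readr::col_character(),
      dataset = readr::col_character(),
      measurement = readr::col_character(),
      value_mm = readr::col_double(),
      valid = readr::col_logical()
    )
  )
  class(out) <- c("measurement_records", class(out))
  out
}
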