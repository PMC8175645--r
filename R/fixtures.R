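#' Packaged orthopaedic trauma case studies
#'
#' Two real-world style trauma cases (Emergency Department admissions for road
#' traffic injuries), each given as the pathway the clinicians planned on
#' admission and the journey that was actually realized. The free-text
#' clinical narrative is encoded as short canonical stage and outcome labels;
#' the mapping is documented on each step's `params` under `narrative`.
#'
#' Case 1 (distal femur fracture): the plan was CT-based classification,
#' preoperative planning for open reduction with plate and screws, the plate
#' fixation itself and full limb recovery. Organizational failure rerouted
#' steps 2-4 (no CT, X-ray-only planning, intramedullary nailing) but the
#' realized journey still reached the expected outcome — a reroute deviation.
#'
#' Case 2 (ankle fracture with alcohol abuse): the plan was the polytrauma
#' protocol, external fixation with CT classification, then definitive
#' fixation with full recovery. Instead the fracture was internally fixed
#' without CT, developed a malunion and needed an osteosynthesis revision,
#' ending in partial articular recovery of the ankle joint — an unintended
#' final condition.
#'
#' @return A list with elements `case1` and `case2`; each is a list holding an
#'   `pathway` ([expected_pathway()]) and a one-row `journey` log tibble.
#' @examples
#' fx <- case_study_fixtures()
#' assess_deviation(fx$case1$pathway, fx$case1$journey)
#' @export
case_study_fixtures <- function() {
  narrative <- function(txt) list(narrative = txt)

  case1_pathway <- expected_pathway(
    name = "distal_femur_fracture_ORIF",
    planned_steps = c(
      "diagnosis_fracture_pattern_classification",
      "preop_planning_CT_plate_screws",
      "surgery_ORIF_plate_screws",
      "full_recovery_limb_geometry"
    ),
    expected_outcome = "full_recovery"
  )
  case1_journey <- journey(
    journey_id = "case_study_1",
    initial = initial_condition(
      admission_diagnosis = "distal_femur_fracture_right",
      expected_outcome = "full_recovery",
      history = c("road_traffic_injury"),
      exam = list(xray_lower_limbs = "distal_femur_fracture",
                  ct_head_thorax_abdomen = "negative"),
      complexity = c("polytrauma"),
      admission_type = "emergency"
    ),
    steps = dplyr::bind_rows(
      journey_step("diagnosis_fracture_pattern_classification", 1,
                   narrative("correct diagnosis and fracture pattern classification")),
      journey_step("under_imaging_no_CT", 2,
                   narrative("under-imaging with no CT scan evaluation of the fracture")),
      journey_step("preop_planning_xray_nail", 3,
                   narrative("preoperative planning based only on X-ray; intramedullary nail indicated")),
      journey_step("surgery_intramedullary_nailing", 4,
                   narrative("surgical intervention with intramedullary nailing and screws"))
    ),
    final = final_state("full_recovery",
                        health_conditions = list(limb_length = "restored")),
    facility = "hospital_A"
  )

  case2_pathway <- expected_pathway(
    name = "ankle_fracture_staged_fixation",
    planned_steps = c(
      "polytrauma_protocol",
      "external_fixation_CT_classification",
      "definitive_fixation"
    ),
    expected_outcome = "full_recovery"
  )
  case2_journey <- journey(
    journey_id = "case_study_2",
    initial = initial_condition(
      admission_diagnosis = "ankle_fracture_right",
      expected_outcome = "full_recovery",
      history = c("road_traffic_injury", "alcohol_abuse"),
      exam = list(GCS = 15, heart_rate_bpm = 100, bp = "140/90",
                  spo2_pct = 99, lactate = 2.7, ethanol = 2.54),
      complexity = c("alcohol_abuse", "polytrauma"),
      admission_type = "emergency"
    ),
    steps = dplyr::bind_rows(
      journey_step("polytrauma_protocol", 1,
                   narrative("polytrauma protocol: X-ray, CT total body, blood samples")),
      journey_step("internal_fixation_no_CT", 2,
                   narrative("incorrect preoperative planning with no CT; improper internal fixation")),
      journey_step("fracture_malunion", 3,
                   narrative("malunion of the fracture")),
      journey_step("osteosynthesis_revision", 4,
                   narrative("osteosynthesis review with bone deformity correction"))
    ),
    final = final_state("partial_articular_recovery_ankle",
                        health_conditions = list(ankle_joint = "partial_recovery")),
    facility = "hospital_A"
  )

  list(
    case1 = list(pathway = case1_pathway, journey = case1_journey),
    case2 = list(pathway = case2_pathway, journey = case2_journey)
  )
}

#' Worked next-step example log
#'
#' A deterministic 100-journey log encoding the canonical next-step worked
#' example: every journey passes through `stage_A`, after which 65 journeys
#' continue to `stage_B`, 25 to `stage_C` and 10 to `stage_D`, before being
#' discharged. Building a knowledge graph on this log with `alpha = 0` yields
#' next-step probabilities of exactly 0.65 / 0.25 / 0.10 from `stage_A`.
#'
#' @return A 100-row journey-log tibble (one cluster).
#' @examples
#' g <- build_graph(extension_example_log())
#' next_step_distribution(g, "stage_A")
#' @export
extension_example_log <- function() {
  successors <- c(rep("stage_B", 65L), rep("stage_C", 25L), rep("stage_D", 10L))
  ini <- initial_condition(
    admission_diagnosis = "example_condition",
    expected_outcome = "discharged",
    admission_type = "elective"
  )
  log <- tibble(
    journey_id = sprintf("ext-%03d", seq_along(successors)),
    initial = rep(list(ini), length(successors)),
    steps = purrr::map(successors, function(nxt) {
      tibble(action = c("stage_A", nxt), params = list(list(), list()),
             t = 1:2, timestamp = NA_character_)
    }),
    final = rep(list(final_state("discharged")), length(successors)),
    facility = NA_character_
  )
  validate_journeys(log)
  log
}
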