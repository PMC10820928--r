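# Builders for small in-memory well tables and study configs used across
# the test files.

make_wells <- function(lab_id = "LabA", plate_id = "P1", week_id = "W1",
                       substance_id = "S1", role = "test", conc_uM = 1,
                       dead_24 = FALSE, dead_120 = FALSE, phenotypes = "",
                       n = 1L, well_offset = 0L) {
  data.frame(
    lab_id = lab_id, plate_id = plate_id, week_id = week_id,
    well_id = sprintf("W%03d", well_offset + seq_len(max(
      n, length(conc_uM), length(dead_24), length(dead_120),
      length(phenotypes)))),
    substance_id = substance_id, role = role, conc_uM = conc_uM,
    dead_24 = dead_24, dead_120 = dead_120, phenotypes = phenotypes,
    stringsAsFactors = FALSE)
}

# one plate: n_dead of 12 vehicle wells dead at 120 hpf, plus a simple
# test series so the plate is complete
make_plate <- function(plate_id, n_dead_veh = 0L, lab_id = "LabA",
                       n_malf_veh = 0L, test_dead = 0L) {
  veh <- make_wells(lab_id = lab_id, plate_id = plate_id, role = "vehicle",
                    substance_id = "vehicle_control", conc_uM = 0, n = 12L,
                    dead_120 = c(rep(TRUE, n_dead_veh),
                                 rep(FALSE, 12L - n_dead_veh)),
                    phenotypes = c(rep("", n_dead_veh),
                                   rep("generic_edema", n_malf_veh),
                                   rep("", 12L - n_dead_veh - n_malf_veh)))
  test <- make_wells(lab_id = lab_id, plate_id = plate_id, role = "test",
                     substance_id = "S1",
                     conc_uM = rep(c(1, 10, 100), each = 4L),
                     dead_120 = seq_len(12L) <= test_dead,
                     well_offset = 12L)
  rbind(veh, test)
}

test_vocabulary <- function(lab_ids = c("LabA", "LabB", "LabC")) {
  do.call(rbind, lapply(lab_ids, function(l) data.frame(
    lab_id = l,
    lab_term = c("generic_edema", "generic_axis_defect",
                 "generic_craniofacial_defect"),
    harmonized_class = c("edema", "axis", "craniofacial"),
    stringsAsFactors = FALSE)))
}

small_study_config <- function(seed = 1L, n_active = 2L, n_inactive = 1L,
                               labs = default_labs()) {
  synthetic_study_config(
    labs = labs,
    substances = default_substances(n_active, n_inactive, n_duplicated = 0L),
    seed = seed)
}
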