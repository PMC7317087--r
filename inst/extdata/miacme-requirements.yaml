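# Declarative MIACME 1.1 requirement table: field path -> requirement level.
# Levels: MUST (missing => error), SHOULD (missing => warning), MAY (ignored).
# Edit this file, not the validator, to change requirement levels.
miacme_version: "1.1"
fields:
  - {path: investigation.title, level: SHOULD}
  - {path: investigation.studies, level: SHOULD}
  - {path: investigation.people, level: SHOULD}
  - {path: investigation.organizations, level: MAY}
  - {path: investigation.publications, level: MAY}
  - {path: investigation.grants, level: MAY}
  - {path: experimental_setup.assay_type, level: MUST}
  - {path: experimental_setup.cell_model, level: MUST}
  - {path: experimental_setup.cell_input, level: SHOULD}
  - {path: experimental_setup.environment, level: SHOULD}
  - {path: experimental_setup.perturbations, level: MAY}
  - {path: imaging_condition.modality, level: MUST}
  - {path: imaging_condition.instrument, level: SHOULD}
  - {path: imaging_condition.channels, level: SHOULD}
  - {path: imaging_condition.time_settings, level: SHOULD}
  - {path: data.raw_data_summary, level: MUST}
  - {path: data.number_of_replicates, level: SHOULD}
  - {path: data.processed_data, level: SHOULD}
  - {path: data.analysis_outputs, level: SHOULD}
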