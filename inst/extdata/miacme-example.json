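{
  "miacme_version": "1.1",
  "investigation": {
    "title": "Single-cell migration of Ba/F3 cells under kinase inhibition (synthetic example)",
    "studies": [
      {
        "identifier": "study-001",
        "description": "Time-lapse imaging of Ba/F3 suspension cells migrating on a fibronectin-coated surface, with and without kinase inhibitor treatment."
      }
    ],
    "people": [
      {"name": "A. Researcher", "role": "principal investigator"},
      {"name": "B. Student", "role": "experimenter"}
    ],
    "organizations": [
      {"name": "Example University, Department of Cell Biology"}
    ],
    "publications": [],
    "grants": [{"identifier": "EX-2020-001", "agency": "Example Funding Agency"}]
  },
  "experimental_setup": {
    "assay_type": {
      "label": "single cell migration assay",
      "source": "OBI",
      "accession": "OBI:0001046"
    },
    "cell_model": [
      {"label": "Ba/F3 cell", "source": "CLO", "accession": "CLO:0001869"}
    ],
    "cell_input": "cells seeded sparsely in suspension over fibronectin-coated glass",
    "environment": {
      "temperature": "37 degree Celsius",
      "co2": "5 percent",
      "medium": "RPMI-1640 with 10 percent FBS and IL-3"
    },
    "perturbations": [
      {
        "agent": {"label": "imatinib", "source": "CHEBI", "accession": "CHEBI:45783"},
        "dose": 10,
        "dose_unit": "micromolar"
      }
    ]
  },
  "imaging_condition": {
    "modality": {
      "label": "phase contrast microscopy",
      "source": "FBbi",
      "accession": "FBbi:00000247"
    },
    "instrument": "inverted wide-field microscope, 10x objective, motorized stage",
    "channels": [{"name": "transmitted light"}],
    "time_settings": {
      "frame_interval": 300,
      "frame_interval_unit": "second",
      "n_frames": 73
    }
  },
  "data": {
    "raw_data_summary": {
      "number_of_images": 73,
      "image_dimensions": "1392x1040",
      "bit_depth": 12
    },
    "number_of_replicates": 3,
    "processed_data": ["per-frame segmentation label images"],
    "analysis_outputs": ["tracking data package: objects, links and tracks tables"]
  }
}
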