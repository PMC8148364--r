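{
  "name": "adan_open_loop",
  "comment": "Hierarchical composition plan for the 86-segment open-loop arterial network: seven top-level lumped subdivisions, merged pairwise in the final step. Leaf entries name representative segment module files; the full published topology and geometry are an optional external input and are not shipped.",
  "children": [
    {
      "name": "heart",
      "children": [
        { "module": "lv_outflow.json" }
      ]
    },
    {
      "name": "head_neck",
      "children": [
        { "module": "common_carotid_L.json" },
        { "module": "common_carotid_R.json" },
        { "module": "vertebral_L.json" },
        { "module": "vertebral_R.json" },
        { "module": "external_carotid_L.json" },
        { "module": "external_carotid_R.json" }
      ]
    },
    {
      "name": "trunk",
      "children": [
        { "module": "ascending_aorta.json" },
        { "module": "aortic_arch.json" },
        { "module": "thoracic_aorta.json" },
        { "module": "abdominal_aorta.json" },
        { "module": "celiac_trunk.json" },
        { "module": "renal_L.json" },
        { "module": "renal_R.json" }
      ]
    },
    {
      "name": "left_arm",
      "children": [
        { "module": "subclavian_L.json" },
        { "module": "axillary_L.json" },
        { "module": "brachial_L.json" },
        { "module": "radial_L.json" },
        { "module": "ulnar_L.json" }
      ]
    },
    {
      "name": "right_arm",
      "children": [
        { "module": "subclavian_R.json" },
        { "module": "axillary_R.json" },
        { "module": "brachial_R.json" },
        { "module": "radial_R.json" },
        { "module": "ulnar_R.json" }
      ]
    },
    {
      "name": "left_leg",
      "children": [
        { "module": "common_iliac_L.json" },
        { "module": "external_iliac_L.json" },
        { "module": "femoral_L.json" },
        { "module": "popliteal_L.json" },
        { "module": "anterior_tibial_L.json" }
      ]
    },
    {
      "name": "right_leg",
      "children": [
        { "module": "common_iliac_R.json" },
        { "module": "external_iliac_R.json" },
        { "module": "femoral_R.json" },
        { "module": "popliteal_R.json" },
        { "module": "anterior_tibial_R.json" }
      ]
    }
  ]
}
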