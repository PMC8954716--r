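# Default synoptic placental pathology scoring scheme.
#
# Seven etiological categories with fixed maximum severity scores
# (14, 4, 11, 5, 6, 5, 6). Each lesion is scored either binary
# (0 absent / 1 present) or graded (0 absent / 1 focal / 2 patchy /
# 3 diffuse). A category's severity is the sum of its member lesion
# grades, capped at max_score. The per-lesion scale assignment is
# editable: it was chosen so member maximum grades reach each category
# cap; in `mvm` and `chronic_inflammation` the member maxima sum above
# the cap, which then binds.
version: "1.0"
mvm_category: mvm
categories:
  - category_id: mvm
    display_name: Maternal vascular malperfusion
    max_score: 14
  - category_id: implantation_site
    display_name: Implantation site abnormalities (maternal decidual arteriopathy)
    max_score: 4
  - category_id: chorioamnionitis
    display_name: Histological chorioamnionitis (ascending intrauterine infection)
    max_score: 11
  - category_id: villous_maldevelopment
    display_name: Placental villous maldevelopment
    max_score: 5
  - category_id: fvm
    display_name: Fetal vascular malperfusion
    max_score: 6
  - category_id: mfi_disturbance
    display_name: Maternal-fetal interface disturbance
    max_score: 5
  - category_id: chronic_inflammation
    display_name: Chronic inflammation
    max_score: 6
lesions:
  - {lesion_id: placental_infarction,            display_name: Placental infarction,                        category_id: mvm,                   scale: graded}
  - {lesion_id: distal_villous_hypoplasia,       display_name: Distal villous hypoplasia,                   category_id: mvm,                   scale: graded}
  - {lesion_id: accelerated_villous_maturation,  display_name: Accelerated villous maturation,              category_id: mvm,                   scale: graded}
  - {lesion_id: syncytial_knots,                 display_name: Increased syncytial knots,                   category_id: mvm,                   scale: graded}
  - {lesion_id: perivillous_fibrin_deposition,   display_name: Perivillous fibrin deposition,               category_id: mvm,                   scale: binary}
  - {lesion_id: villous_agglutination,           display_name: Villous agglutination,                       category_id: mvm,                   scale: binary}
  - {lesion_id: retroplacental_hematoma,         display_name: Retroplacental hematoma,                     category_id: mvm,                   scale: binary}
  - {lesion_id: insufficient_vessel_remodeling,  display_name: Insufficient spiral artery remodeling,       category_id: implantation_site,     scale: graded}
  - {lesion_id: fibrinoid_necrosis,              display_name: Fibrinoid necrosis of decidual vessels,      category_id: implantation_site,     scale: binary}
  - {lesion_id: maternal_inflammatory_response,  display_name: Maternal inflammatory response (stage),      category_id: chorioamnionitis,      scale: graded}
  - {lesion_id: fetal_inflammatory_response,     display_name: Fetal inflammatory response (stage),         category_id: chorioamnionitis,      scale: graded}
  - {lesion_id: subchorionitis,                  display_name: Acute subchorionitis,                        category_id: chorioamnionitis,      scale: graded}
  - {lesion_id: funisitis,                       display_name: Funisitis,                                   category_id: chorioamnionitis,      scale: binary}
  - {lesion_id: chorionic_plate_vasculitis,      display_name: Chorionic plate vasculitis,                  category_id: chorioamnionitis,      scale: binary}
  - {lesion_id: delayed_villous_maturation,      display_name: Delayed villous maturation,                  category_id: villous_maldevelopment, scale: graded}
  - {lesion_id: chorangiosis,                    display_name: Chorangiosis,                                category_id: villous_maldevelopment, scale: binary}
  - {lesion_id: chorangiomas,                    display_name: Chorangiomas,                                category_id: villous_maldevelopment, scale: binary}
  - {lesion_id: avascular_fibrotic_villi,        display_name: Avascular fibrotic villi,                    category_id: fvm,                   scale: graded}
  - {lesion_id: thrombosis,                      display_name: Fetal vessel thrombosis,                     category_id: fvm,                   scale: binary}
  - {lesion_id: intramural_fibrin_deposition,    display_name: Intramural fibrin deposition,                category_id: fvm,                   scale: binary}
  - {lesion_id: karyorrhexis,                    display_name: Villous stromal-vascular karyorrhexis,       category_id: fvm,                   scale: binary}
  - {lesion_id: intervillous_thrombi,            display_name: Intervillous thrombi,                        category_id: mfi_disturbance,       scale: graded}
  - {lesion_id: massive_perivillous_fibrin_pattern, display_name: Massive perivillous fibrin deposition pattern, category_id: mfi_disturbance,  scale: binary}
  - {lesion_id: maternal_floor_infarction_pattern,  display_name: Maternal floor infarction pattern,        category_id: mfi_disturbance,       scale: binary}
  - {lesion_id: villitis_unknown_etiology,       display_name: Villitis of unknown etiology,                category_id: chronic_inflammation,  scale: graded}
  - {lesion_id: chronic_plasma_cell_deciduitis,  display_name: Chronic plasma cell deciduitis,              category_id: chronic_inflammation,  scale: graded}
  - {lesion_id: chronic_intervillositis,         display_name: Chronic histiocytic intervillositis,         category_id: chronic_inflammation,  scale: binary}
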