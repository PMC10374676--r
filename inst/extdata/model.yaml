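# Population constants of the hematopoiesis model. Units: rates in 1/day,
# counts in 1e9/L, sensitivities dimensionless. Individual defaults are the
# population centres around which per-patient parameters scatter.
model:
  # normal (homeostatic) blood counts
  ANC_nor: 3.0
  PLT_nor: 250.0
  LYM_nor: 2.0
  MON_nor: 0.5
  # stem cell / niche
  k_S: 0.5          # stem-cell turnover
  b_MKC_S: 0.2      # megakaryocyte-mass feedback on stem-cell activation
  k_O: 0.05         # osteoblast recovery
  k_D: 0.10         # dormant-precursor replenishment
  # granulopoiesis
  k_CMP: 0.6
  k_Gp: 0.7
  k_mat: 1.1111111  # 4 stages / 3.6 d post-mitotic maturation
  k_ANC: 2.3        # blood neutrophil clearance
  b_G_amp: 0.8      # G-CSF amplification of granulopoietic influx
  # thrombopoiesis
  k_CM: 0.5
  k_pl: 1.4         # ploidy-class transit
  k_PPT: 1.0
  tau_PLT: 9.0      # platelet lifespan (days), Erlang-10 chain
  # lymphocytes / monocytes
  k_Lp: 0.25
  k_L: 0.15
  k_MON: 1.0
  # cytokines
  h_TPO: 1.0        # biphasic TPO shape
  s_TPO: 0.1        # biphasic TPO suppression weight
  k_G_ren: 2.0      # renal G-CSF clearance
  k_G_anc: 4.0      # neutrophil-mediated G-CSF clearance (max)
  k_T_ren: 0.5      # renal TPO clearance
  w_mkc: 0.3        # megakaryocyte weight in TPO-clearing cell mass
  # chemotherapy pharmacodynamics scaling
  f_kill_S: 0.1     # fraction of stem pool in cycle
  f_kill_O: 0.03    # osteoblast vulnerability (drives long-term toxicity)
  f_kill_L: 0.7     # lymphoid progenitor vulnerability
  # per-drug lineage vulnerability weights (granulopoietic / thrombopoietic
  # branch kill multipliers; shared compartments see unweighted kill)
  w_gran_oxa: 0.5
  w_gran_fu: 1.3
  w_gran_iri: 1.3
  w_gran_doc: 1.5
  w_thr_oxa: 1.6
  w_thr_fu: 0.5
  w_thr_iri: 0.5
  w_thr_doc: 0.3
  # regulation clamps
  z_min: 0.1
  z_max: 10.0
  plt_prod_scale: 1.0
individual:
  # per-patient parameters (population centres)
  b_S_act: 1.0       # G-CSF action on stem cells
  b_A_CM: 1.0        # G-CSF action on CMP and CM progenitors
  b_MKC64: 1.0       # TPO action on ploidy-64 -> proplatelet transition
  w_PLC: 2.0         # max TPO elimination by circulating platelets (1/day)
  d_Osteo_loss: 0.05 # dormant-precursor loss without osteoblast support
  PD_oxali: 1.0      # linear kill coefficients (L/mg/day)
  PD_5FU: 0.35
  PD_iri: 0.5
  PD_doc: 0.4
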