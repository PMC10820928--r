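lab_id,lab_term,harmonized_class
LabA,Abnormal_heartbeat,other
LabA,Abnormal_length,trunk
LabA,Abnormal_pigmentation,pigment
LabA,Absence_heartbeat,other
LabA,Altered_jaw_morphology,craniofacial
LabA,Altered_snout,craniofacial
LabA,Curved_axis,axis
LabA,Decreased_absent_pigmentation,pigment
LabA,Delayed_Hatching,other
LabA,Malformed__disorganized_or_missing_somites,trunk
LabA,Malformed_or_missing_caudal_fin,trunk
LabA,Malformed_or_missing_otic_vesicle,craniofacial
LabA,Malformed_or_missing_trunk,trunk
LabA,Notochord_malformation,axis
LabA,Others,other
LabA,Presence_of_head_Edema,edema
LabA,Presence_of_pericardial_Edema,edema
LabA,Smaller_abnormal_eye_shape,craniofacial
LabA,Smaller_abnormal_head_shape,craniofacial
LabA,Yolk_opacity,other
LabA,Yolk_sac_Edema,edema
LabB,Abnormal axial bend (AXIS),axis
LabB,Abnormal brain region (BRN_),craniofacial
LabB,Abnormal notochord (NC__),axis
LabB,"Abnormal swim bladder, muscle pattern, blood circulation (MUSC)",other
LabB,Abnormal touch response in the caudal fin (TCHR),other
LabB,Defects in the Craniofacial region (CRAN),craniofacial
LabB,Defects in the lower trunk region (LTRK),trunk
LabB,Defects on the skin (SKIN),other
LabB,"Edema of the heart, yolk sac or brain region (EDEM)",edema
LabC,Axis__curvature_of_body_axis,axis
LabC,Craniofacial__edema,edema
LabC,Craniofacial__jaw_defects,craniofacial
LabC,Craniofacial__snout_defects,craniofacial
LabC,fin_absence,trunk
LabC,necrosis,other
LabC,notochord_defect,axis
LabC,otoliths_defects,craniofacial
LabC,scoliosis,axis
LabC,tail_bending,axis
LabC,Unhatched,other
LabC,Yolk_sac__Edema,edema
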