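code,text
HTN_SEVERE_URGENT,This woman has evidence of severe hypertension. Call ambulance and refer patient to hospital urgently.
HTN_REFER,This woman has raised blood pressure or an elevated shock index. Refer her to the primary health centre doctor for review.
ANEMIA_SEVERE_URGENT,This woman has severe anemia. Refer her to hospital urgently for assessment and possible transfusion.
ANEMIA_REFER,This woman has moderate to severe anemia. Refer her to the primary health centre for iron therapy and follow-up.
ANEMIA_ADVICE,This woman has mild anemia. Counsel on iron and folic acid supplementation and diet; recheck hemoglobin at the next visit.
DM_OVERT_URGENT,This woman's glucose level suggests overt diabetes. Refer her to hospital urgently.
GDM_REFER,This woman's oral glucose tolerance test suggests gestational diabetes. Refer her to the primary health centre doctor.
MISSING_GDM_SCREEN,Gestational diabetes screening has not been recorded. Arrange screening.
MISSING_OGTT,No oral glucose tolerance test is on record. Arrange a nonfasting OGTT with 2-hour glucose measurement.
MISSING_IFA,Iron and folic acid supplementation has not been supplied. Arrange supply and counsel on adherence.
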