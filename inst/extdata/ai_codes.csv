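code_id,level,specialty,description,points
AI-101,I,Radiology - X-ray,Assistive AI triage of chest X-ray images (flags abnormal vs. normal exams for the radiologist),50
AI-102,I,Ultrasound imaging,Assistive AI feature detection in ultrasound (highlights organ contours or lesions for the physician),60
AI-201,II,Laboratory diagnostics,Augmentative AI analysis of laboratory results (interprets complex patterns and suggests diagnoses or further tests),80
AI-202,II,Pathology - Histology,Augmentative AI slide review support (marks suspicious cells or regions on digitized pathology slides),150
AI-301,III,Cardiology - ECG,Autonomous AI interpretation of ECG with preliminary report (physician oversight available for confirmation),100
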