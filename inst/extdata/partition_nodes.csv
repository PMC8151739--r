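partition,region,node
A1,Posterior cervical region,Fourth cervical vertebra
A2,Occipital region,Occipital eminence
A3,Posterior parietal region,Parietal foramen
B1,Lateral cervical region,Intersection of larynx and neck edge
B2,Jaw region,Angle of mandible
B3,Temporal bone region,Zygomatic arch
B4,Lateral parietal region,Parietal tuber
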