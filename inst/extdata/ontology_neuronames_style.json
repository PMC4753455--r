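{
 "name": "brain",
 "acronym": "Br",
 "children": [
  {
   "name": "forebrain",
   "acronym": "FB",
   "children": [
    {
     "name": "telencephalon",
     "acronym": "Tel",
     "children": [
      {
       "name": "cerebral_cortex",
       "acronym": "Cx",
       "children": [
        {
         "name": "neocortex",
         "acronym": "NCx",
         "labels": [
          1
         ]
        },
        {
         "name": "entorhinal_cortex",
         "acronym": "ECx",
         "labels": [
          10
         ]
        },
        {
         "name": "piriform_cortex",
         "acronym": "PCx",
         "labels": [
          11
         ]
        }
       ]
      },
      {
       "name": "hippocampal_region",
       "acronym": "HiR",
       "children": [
        {
         "name": "hippocampus_proper",
         "acronym": "HC",
         "labels": [
          4
         ]
        },
        {
         "name": "dentate_gyrus",
         "acronym": "DG",
         "labels": [
          12
         ]
        },
        {
         "name": "subiculum",
         "acronym": "Sub",
         "labels": [
          13
         ]
        }
       ]
      },
      {
       "name": "basal_ganglia",
       "acronym": "BG",
       "children": [
        {
         "name": "striatum",
         "acronym": "Str",
         "labels": [
          3
         ]
        },
        {
         "name": "globus_pallidus",
         "acronym": "GP",
         "labels": [
          14
         ]
        }
       ]
      },
      {
       "name": "septal_region",
       "acronym": "Sep",
       "labels": [
        15
       ]
      },
      {
       "name": "amygdala",
       "acronym": "Amg",
       "labels": [
        16
       ]
      },
      {
       "name": "subcortical_white_matter",
       "acronym": "WM",
       "children": [
        {
         "name": "corpus_callosum",
         "acronym": "cc",
         "labels": [
          2
         ]
        },
        {
         "name": "internal_capsule",
         "acronym": "ic",
         "labels": [
          17
         ]
        },
        {
         "name": "anterior_commissure",
         "acronym": "ac",
         "labels": [
          18
         ]
        }
       ]
      }
     ]
    },
    {
     "name": "diencephalon",
     "acronym": "Di",
     "children": [
      {
       "name": "thalamus",
       "acronym": "Thal",
       "labels": [
        5
       ]
      },
      {
       "name": "hypothalamus",
       "acronym": "Hy",
       "labels": [
        19
       ]
      },
      {
       "name": "epithalamus",
       "acronym": "Epi",
       "labels": [
        20
       ]
      },
      {
       "name": "subthalamus",
       "acronym": "SubTh",
       "labels": [
        21
       ]
      }
     ]
    }
   ]
  },
  {
   "name": "midbrain",
   "acronym": "MB",
   "children": [
    {
     "name": "tectum",
     "acronym": "Tc",
     "children": [
      {
       "name": "superior_colliculus",
       "acronym": "SC",
       "labels": [
        22
       ]
      },
      {
       "name": "inferior_colliculus",
       "acronym": "IC",
       "labels": [
        23
       ]
      }
     ]
    },
    {
     "name": "tegmentum",
     "acronym": "Tg",
     "labels": [
      24
     ]
    }
   ]
  },
  {
   "name": "hindbrain",
   "acronym": "HB",
   "children": [
    {
     "name": "cerebellum",
     "acronym": "Cb",
     "children": [
      {
       "name": "cerebellar_cortex",
       "acronym": "CbCx",
       "labels": [
        25
       ]
      },
      {
       "name": "cerebellar_nuclei",
       "acronym": "CbN",
       "labels": [
        26
       ]
      }
     ]
    },
    {
     "name": "pons",
     "acronym": "Po",
     "labels": [
      27
     ]
    },
    {
     "name": "medulla_oblongata",
     "acronym": "MO",
     "labels": [
      28
     ]
    }
   ]
  },
  {
   "name": "other_brain",
   "acronym": "Oth",
   "labels": [
    6
   ]
  }
 ]
}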