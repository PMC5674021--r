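landscape_id,county,class_label,mean_size_ha,n_patches,total_area_ha,forest_type
NORTH,alder,C1,3,120,360,total
NORTH,alder,C2,15,40,600,total
NORTH,alder,C3,70,12,840,total
NORTH,alder,C4,300,3,900,total
NORTH,birch,C1,3,80,200,total
NORTH,birch,C2,15,30,480,total
NORTH,birch,C3,70,10,680,total
NORTH,birch,C4,300,2,650,total
NORTH,alder,C1,1,60,60,core
NORTH,alder,C2,8,40,320,core
NORTH,alder,C3,50,12,600,core
NORTH,alder,C4,250,3,750,core
NORTH,birch,C1,1,40,40,core
NORTH,birch,C2,8,30,240,core
NORTH,birch,C3,50,10,500,core
NORTH,birch,C4,250,2,540,core
SOUTH,cedar,C1,3,400,1200,total
SOUTH,cedar,C2,15,90,1350,total
SOUTH,cedar,C3,70,6,420,total
SOUTH,cedar,C4,300,0,0,total
SOUTH,dogwood,C1,3,350,1050,total
SOUTH,dogwood,C2,15,70,1050,total
SOUTH,dogwood,C3,70,4,280,total
SOUTH,dogwood,C4,300,0,0,total
SOUTH,cedar,C1,1,200,200,core
SOUTH,cedar,C2,8,90,720,core
SOUTH,cedar,C3,45,6,270,core
SOUTH,cedar,C4,250,0,0,core
SOUTH,dogwood,C1,1,180,180,core
SOUTH,dogwood,C2,8,70,560,core
SOUTH,dogwood,C3,45,4,180,core
SOUTH,dogwood,C4,250,0,0,core
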