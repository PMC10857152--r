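# Markups fiducial file version = 4.11
# CoordinateSystem = LPS
# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID
vtkMRMLMarkupsFiducialNode_1,-12.4,-88.2,31.0,0,0,0,1,1,1,0,F-1,,
vtkMRMLMarkupsFiducialNode_2,45.1,-70.6,52.3,0,0,0,1,1,1,0,F-2,,
vtkMRMLMarkupsFiducialNode_3,-58.9,-45.0,60.2,0,0,0,1,1,1,0,F-3,,
vtkMRMLMarkupsFiducialNode_4,3.2,-20.7,83.5,0,0,0,1,1,1,0,F-4,,
vtkMRMLMarkupsFiducialNode_5,66.0,-18.3,41.8,0,0,0,1,1,1,0,F-5,,
vtkMRMLMarkupsFiducialNode_6,-70.2,-10.9,28.4,0,0,0,1,1,1,0,F-6,,
vtkMRMLMarkupsFiducialNode_7,30.7,-52.5,70.1,0,0,0,1,1,1,0,F-7,,
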